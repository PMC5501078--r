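# Mutational spectra: six pyrimidine-referenced substitution classes, the
# 96 trinucleotide-context channels, reference-frequency normalization for
# heatmap display, rainfall (inter-mutation) distances, sliding-window
# cluster (kataegis) detection, and windowed coverage summaries.

check_snvs <- function(snvs) {
  assert_that(all(nchar(snvs$ref) == 1L & nchar(snvs$alt) == 1L),
              "spectrum input must be SNVs (1 bp ref and alt)")
  invisible(snvs)
}

#' Build six-class and 96-context mutational spectra
#'
#' Substitutions with a purine reference base are reverse-complemented into
#' the pyrimidine-referenced classes. The 96-channel counts are normalized
#' for display as `log10((count / total) / ref_context_freq)`, where
#' `ref_context_freq` is the strand-collapsed trinucleotide frequency of
#' the reference; zero cells receive a pseudo-count of 0.5 before the log.
#' SNVs at contig edges (no flanking base) are excluded and counted in
#' `n_excluded`.
#'
#' @param snvs data.frame with `chrom, pos, ref, alt` (SNVs only).
#' @param reference `DNAStringSet` with the reference sequences.
#' @return Object of class `spectrum_matrix`: list with `counts6` (named
#'   length-6), `counts96` (named length-96), `ref_context_freq` (named
#'   length-32, sums to 1), `normalized96` (named length-96, log10 scale),
#'   `n_excluded`.
#' @export
build_spectrum <- function(snvs, reference) {
  check_snvs(snvs)
  chan <- rep(NA_character_, nrow(snvs))
  mismatch <- character(0)
  for (i in seq_len(nrow(snvs))) {
    chromseq <- reference[[snvs$chrom[i]]]
    L <- length(chromseq)
    p <- snvs$pos[i]
    refbase <- as.character(Biostrings::subseq(chromseq, p, p))
    if (refbase != snvs$ref[i]) {
      mismatch <- c(mismatch, sprintf("%s:%d %s>%s (reference has %s)",
                                      snvs$chrom[i], p, snvs$ref[i],
                                      snvs$alt[i], refbase))
      next
    }
    if (p <= 1L || p >= L) next  # contig edge: no trinucleotide context
    p5 <- as.character(Biostrings::subseq(chromseq, p - 1L, p - 1L))
    p3 <- as.character(Biostrings::subseq(chromseq, p + 1L, p + 1L))
    if (p5 %in% BASES && p3 %in% BASES) {
      chan[i] <- snv_channel(snvs$ref[i], snvs$alt[i], p5, p3)
    }
  }
  if (length(mismatch) > 0L) {
    stop_named("crossvar_reference_mismatch",
               "reference mismatch at %d SNV site(s): %s",
               length(mismatch), paste(mismatch, collapse = "; "))
  }
  n_excluded <- sum(is.na(chan))
  channels <- context_channels()
  counts96 <- setNames(as.numeric(table(factor(chan, levels = channels))),
                       channels)
  cls <- vapply(channels, function(x) channel_parts(x)$class, character(1))
  counts6 <- vapply(SUB_CLASSES, function(k) sum(counts96[cls == k]),
                    numeric(1))

  # strand-collapsed reference trinucleotide frequencies
  tri_all <- colSums(Biostrings::trinucleotideFrequency(reference))
  trin <- pyrimidine_trinucs()
  freq <- setNames(numeric(32L), trin)
  for (t in names(tri_all)) {
    ct <- collapse_trinuc(t)
    if (ct %in% trin) freq[ct] <- freq[ct] + tri_all[[t]]
  }
  freq <- freq / sum(freq)

  total <- sum(counts96)
  cnt <- counts96
  cnt[cnt == 0] <- 0.5
  ctx_tri <- vapply(channels, function(x) channel_parts(x)$trinuc,
                    character(1))
  normalized96 <- log10((cnt / max(total, 1)) / freq[ctx_tri])
  names(normalized96) <- channels
  structure(list(counts6 = counts6, counts96 = counts96,
                 ref_context_freq = freq, normalized96 = normalized96,
                 n_excluded = n_excluded),
            class = "spectrum_matrix")
}

#' @export
print.spectrum_matrix <- function(x, ...) {
  cat(sprintf("Mutational spectrum: %d SNVs (%d excluded at edges)\n",
              sum(x$counts6), x$n_excluded))
  print(round(x$counts6))
  invisible(x)
}

#' Inter-mutation (rainfall) distances
#'
#' @param snvs SNV data.frame (`chrom, pos, ref, alt`), any order.
#' @return data.frame `chrom, pos, distance, class`, sorted by (chrom, pos);
#'   `distance` to the previous SNV on the same chromosome is `NA` for the
#'   first SNV of each chromosome.
#' @export
rainfall <- function(snvs) {
  check_snvs(snvs)
  s <- snvs[order(snvs$chrom, snvs$pos), , drop = FALSE]
  dist <- rep(NA_integer_, nrow(s))
  if (nrow(s) > 1L) {
    same <- s$chrom[-1L] == s$chrom[-nrow(s)]
    d <- diff(s$pos)
    dist[-1L][same] <- d[same]
  }
  cls <- ifelse(s$ref %in% c("C", "T"), paste0(s$ref, ">", s$alt),
                paste0(comp_base(s$ref), ">", comp_base(s$alt)))
  data.frame(chrom = s$chrom, pos = s$pos, distance = dist, class = cls,
             stringsAsFactors = FALSE)
}

#' Detect clustered hypermutation (kataegis) by sliding window
#'
#' A window qualifies under a rule `(window_bp, min_snvs)` when at least
#' `min_snvs` SNVs fall within a span of at most `window_bp` bases
#' (two-pointer sweep anchored on SNV positions). Overlapping qualifying
#' spans of one rule on one chromosome are merged into maximal windows.
#'
#' @param snvs SNV data.frame (`chrom, pos`).
#' @param rules List of `c(window_bp, min_snvs)` pairs; defaults to the
#'   two published start parameters: 8 SNVs in 160 bp and 50 SNVs in
#'   5000 bp.
#' @return data.frame `chrom, start, end, n_snvs, window_bp, min_snvs`.
#' @export
detect_clusters <- function(snvs, rules = list(c(160, 8), c(5000, 50))) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_snvs = integer(0),
                      window_bp = integer(0), min_snvs = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(snvs) == 0L) return(empty)
  out <- list()
  for (rule in rules) {
    w <- as.integer(rule[1]); k <- as.integer(rule[2])
    for (ch in unique(snvs$chrom)) {
      pos <- sort(snvs$pos[snvs$chrom == ch])
      n <- length(pos)
      if (n < k) next
      spans <- NULL
      j <- 1L
      for (i in seq_len(n)) {
        if (j < i) j <- i
        while (j < n && pos[j + 1L] - pos[i] + 1L <= w) j <- j + 1L
        if (j - i + 1L >= k) {
          spans <- rbind(spans, c(pos[i], pos[j]))
        }
      }
      if (is.null(spans)) next
      # merge overlapping qualifying spans into maximal windows
      merged <- list()
      cur <- spans[1L, ]
      for (r in seq_len(nrow(spans))[-1L]) {
        if (spans[r, 1L] <= cur[2L]) {
          cur[2L] <- max(cur[2L], spans[r, 2L])
        } else {
          merged[[length(merged) + 1L]] <- cur
          cur <- spans[r, ]
        }
      }
      merged[[length(merged) + 1L]] <- cur
      for (m in merged) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = m[1L], end = m[2L],
          n_snvs = sum(pos >= m[1L] & pos <= m[2L]),
          window_bp = w, min_snvs = k, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res[order(res$window_bp, res$chrom, res$start), , drop = FALSE]
}

#' Mean coverage in sliding windows
#'
#' @param coverage Numeric per-base coverage vector (position = index).
#' @param window,step Window and step sizes in bp (defaults 150000 /
#'   75000).
#' @param cap Export cap on the reported mean (default 100); the raw mean
#'   is kept in `mean_coverage`, the capped value in `export`.
#' @param chrom Chromosome label for the output rows.
#' @param path Optional TSV output path (writes the capped values).
#' @return data.frame `chrom, start, end, mean_coverage, export`.
#' @export
windowed_coverage <- function(coverage, window = 150000L, step = 75000L,
                              cap = 100, chrom = "chr1", path = NULL) {
  L <- length(coverage)
  starts <- seq.int(1L, max(1L, L), by = step)
  starts <- starts[starts <= L]
  rows <- lapply(starts, function(s) {
    e <- min(s + window - 1L, L)
    m <- mean(coverage[s:e])
    data.frame(chrom = chrom, start = s, end = e, mean_coverage = m,
               export = min(m, cap), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    write.table(out[, c("chrom", "start", "end", "export")], path,
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
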