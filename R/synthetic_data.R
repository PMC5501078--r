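# Synthetic-data generator: emulates every input the pipeline consumes
# (reference FASTA + gene BED, per-platform per-caller VCF call sets with a
# pileup support table, a population panel, and structural-variant inputs),
# with recorded ground truth so every downstream stage can be scored.

#' Simulation configuration
#'
#' Defaults describe a desk-scale version of a two-platform (WES + WGS)
#' matched tumor/normal design: a 1 Mb single-chromosome genome, 50 genes,
#' tumor purity 0.30 (a microsatellite-unstable-like sample), 200 somatic
#' SNVs drawn from a mutational-signature mixture, and a 1092-sample
#' population panel.
#'
#' @param seed Integer seed; all `simulate_*` output is a pure function of
#'   the configuration including this seed.
#' @param genome_length Reference length in bp.
#' @param n_genes Number of non-overlapping genes.
#' @param exons_per_gene,exon_length Ranges (min, max) for uniform draws.
#' @param purity Tumor cell fraction in (0, 1].
#' @param n_somatic_snvs,n_germline_snvs SNV counts to plant.
#' @param signature_mixture Named weights over columns of `catalog`
#'   (normalized to sum 1). Default: 60/40 mix of the two synthetic
#'   signatures in [synthetic_catalog()].
#' @param catalog Signature catalog (96 x k matrix); default
#'   [synthetic_catalog()].
#' @param planted_clusters List of `list(position, n_snvs, span_bp)` hyper-
#'   mutation clusters added on top of `n_somatic_snvs`.
#' @param platform_sensitivity Named list `WES`/`WGS` of per-caller
#'   detection probabilities.
#' @param maf_concentration Beta concentration for somatic tumor MAFs
#'   (mean `purity / 2`); `Inf` makes every somatic MAF exactly
#'   `purity / 2` (the noise-free limit).
#' @param read_noise If `TRUE`, alt reads are binomial draws at the true
#'   MAF; if `FALSE`, `round(depth * maf)` (noise-free support).
#' @param mean_depth Named per-platform mean sequencing depth.
#' @param fp_private Named per-platform count of injected platform-private
#'   false-positive calls (default 0).
#' @param panel_samples Population-panel size (default 1092).
#' @param panel_rate_per_bp Per-sample, per-exonic-bp non-synonymous variant
#'   rate before the per-gene multiplier.
#' @param gene_rate_multipliers Optional numeric vector (length `n_genes`)
#'   of per-gene panel rate multipliers; default gamma-distributed so genes
#'   span conserved to hypervariable.
#' @param sv List of planted structural-variant counts:
#'   `n_germline_ins`, `n_somatic_ins`, and per-type germline/somatic
#'   counts for deletions, inversions, tandem duplications, translocations.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 1000000L,
                       n_genes = 50L,
                       exons_per_gene = c(2L, 8L),
                       exon_length = c(100L, 300L),
                       purity = 0.30,
                       n_somatic_snvs = 200L,
                       n_germline_snvs = 500L,
                       signature_mixture = NULL,
                       catalog = synthetic_catalog(),
                       planted_clusters = list(),
                       platform_sensitivity = list(
                         WES = c(gatk = 1, samtools = 1, dibayes = 1),
                         WGS = c(gatk = 1, samtools = 1)),
                       maf_concentration = 100,
                       read_noise = TRUE,
                       mean_depth = c(WES = 100, WGS = 40),
                       fp_private = c(WES = 0L, WGS = 0L),
                       panel_samples = 1092L,
                       panel_rate_per_bp = 5e-4,
                       gene_rate_multipliers = NULL,
                       sv = list(n_germline_ins = 3L, n_somatic_ins = 2L,
                                 deletion = c(germline = 3L, somatic = 3L),
                                 inversion = c(germline = 2L, somatic = 2L),
                                 tandem_duplication = c(germline = 2L,
                                                        somatic = 2L),
                                 translocation = c(germline = 1L,
                                                   somatic = 2L))) {
  if (is.null(signature_mixture)) {
    signature_mixture <- setNames(c(0.6, 0.4), colnames(catalog)[1:2])
  }
  assert_that(purity > 0 && purity <= 1, "purity must be in (0, 1]")
  assert_that(all(signature_mixture >= 0) && sum(signature_mixture) > 0,
              "signature mixture weights must be non-negative, not all zero")
  assert_that(all(names(signature_mixture) %in% colnames(catalog)),
              "signature mixture names must match catalog columns")
  assert_that(n_somatic_snvs >= 0 && n_germline_snvs >= 0,
              "variant counts must be >= 0")
  signature_mixture <- signature_mixture / sum(signature_mixture)
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              n_genes = as.integer(n_genes), exons_per_gene = exons_per_gene,
              exon_length = exon_length, purity = purity,
              n_somatic_snvs = as.integer(n_somatic_snvs),
              n_germline_snvs = as.integer(n_germline_snvs),
              signature_mixture = signature_mixture, catalog = catalog,
              planted_clusters = planted_clusters,
              platform_sensitivity = platform_sensitivity,
              maf_concentration = maf_concentration,
              read_noise = read_noise, mean_depth = mean_depth,
              fp_private = fp_private,
              panel_samples = as.integer(panel_samples),
              panel_rate_per_bp = panel_rate_per_bp,
              gene_rate_multipliers = gene_rate_multipliers, sv = sv)
  class(cfg) <- "sim_config"
  cfg
}

#' Synthetic mutational-signature catalog
#'
#' Three synthetic 96-channel profiles loosely patterned on well-known
#' processes: `SBS_deam` (C>T at NpCpG-like contexts, spontaneous
#' deamination), `SBS_tg` (T>G with a 5' C, the acid-reflux-associated
#' pattern seen in gastric/esophageal tumors), and `SBS_flat` (uniform).
#' Columns sum to 1.
#'
#' @return 96 x 3 numeric matrix, rows named by [context_channels()].
#' @export
synthetic_catalog <- function() {
  ch <- context_channels()
  parts <- lapply(ch, function(x) channel_parts(x))
  cls <- vapply(parts, `[[`, character(1), "class")
  p5 <- vapply(parts, `[[`, character(1), "p5")
  p3 <- vapply(parts, `[[`, character(1), "p3")
  deam <- ifelse(cls == "C>T", ifelse(p3 == "G", 8, 1), 0.05)
  tg <- ifelse(cls == "T>G" & p5 == "C", 10, ifelse(cls == "T>G", 1, 0.05))
  flat <- rep(1, 96)
  m <- cbind(SBS_deam = deam / sum(deam), SBS_tg = tg / sum(tg),
             SBS_flat = flat / sum(flat))
  rownames(m) <- ch
  m
}

#' Simulate a reference genome and gene model
#'
#' Generates a uniform-composition random reference and packs `n_genes`
#' non-overlapping genes (each a run of exons with intronic gaps) into it.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory; when given, writes `reference.fa` and
#'   `genes.bed` (exon-per-row BED, gene symbol in the name column).
#' @return List with `reference` (`DNAStringSet`, one sequence `chr1`),
#'   `exons` (data.frame `gene, chrom, start, end`, 1-based inclusive),
#'   and, if written, `fasta_path` / `bed_path`.
#' @export
simulate_reference <- function(config, dir = NULL) {
  set.seed(child_seed(config$seed, "reference"))
  L <- config$genome_length
  seq <- paste(sample(BASES, L, replace = TRUE), collapse = "")
  reference <- Biostrings::DNAStringSet(seq)
  names(reference) <- "chr1"

  exons <- data.frame(gene = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  if (config$n_genes > 0L) {
    n_ex <- sample(seq(config$exons_per_gene[1], config$exons_per_gene[2]),
                   config$n_genes, replace = TRUE)
    ex_len <- lapply(n_ex, function(k)
      sample(seq(config$exon_length[1], config$exon_length[2]), k,
             replace = TRUE))
    intron <- 200L
    gene_span <- vapply(ex_len, function(l)
      sum(l) + intron * (length(l) - 1L), numeric(1))
    total_needed <- sum(gene_span) + 100L * (config$n_genes + 1L)
    if (total_needed > L) {
      stop_named("crossvar_packing_error",
                 "cannot pack %d genes (%d bp needed) into %d bp",
                 config$n_genes, total_needed, L)
    }
    slack <- L - sum(gene_span)
    gaps <- as.integer(stats::rmultinom(1, slack - (config$n_genes + 1L) * 50L,
                                        rep(1, config$n_genes + 1L))) + 50L
    cursor <- 0L
    rows <- list()
    for (g in seq_len(config$n_genes)) {
      cursor <- cursor + gaps[g]
      start <- cursor + 1L
      for (e in seq_along(ex_len[[g]])) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = sprintf("GENE%03d", g), chrom = "chr1",
          start = start, end = start + ex_len[[g]][e] - 1L,
          stringsAsFactors = FALSE)
        start <- start + ex_len[[g]][e] + intron
      }
      cursor <- cursor + gene_span[g]
    }
    exons <- do.call(rbind, rows)
  }
  out <- list(reference = reference, exons = exons)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$fasta_path <- file.path(dir, "reference.fa")
    Biostrings::writeXStringSet(reference, out$fasta_path)
    out$bed_path <- file.path(dir, "genes.bed")
    write_gene_bed(exons, out$bed_path)
  }
  out
}

#' Write / read an exon-per-row gene BED
#'
#' BED uses 0-based half-open coordinates; conversion to the package's
#' 1-based inclusive convention happens here at the boundary.
#'
#' @param exons data.frame `gene, chrom, start, end` (1-based inclusive).
#' @param path BED path.
#' @return `path` invisibly (write); exon data.frame (read).
#' @export
write_gene_bed <- function(exons, path) {
  if (nrow(exons) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(exons$chrom,
                               IRanges::IRanges(exons$start, exons$end),
                               name = exons$gene)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_gene_bed
#' @export
read_gene_bed <- function(path) {
  if (length(readLines(path, n = 1L, warn = FALSE)) == 0L) {
    return(data.frame(gene = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  }
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(gene = gr$name,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

# Integer-coded trinucleotide index (1..64) at every internal position.
trinuc_index <- function(seq_chr) {
  code <- match(strsplit(seq_chr, "", fixed = TRUE)[[1]], BASES)
  n <- length(code)
  (code[1:(n - 2L)] - 1L) * 16L + (code[2:(n - 1L)] - 1L) * 4L +
    code[3:n]
}

trinuc_from_index <- function(idx) {
  i <- idx - 1L
  paste0(BASES[i %/% 16L + 1L], BASES[(i %/% 4L) %% 4L + 1L],
         BASES[i %% 4L + 1L])
}

#' Simulate per-platform, per-caller tumor/normal call sets
#'
#' Somatic SNVs are placed at reference positions whose trinucleotide
#' context (on either strand) matches a channel drawn from the configured
#' signature mixture; clonal heterozygous somatic MAFs are Beta-distributed
#' around `purity / 2`, germline MAFs around 0.5 (het) or 1.0 (hom). Every
#' true variant is emitted into each platform/caller call set with that
#' caller's detection probability, and a pileup support table records
#' depth/alt reads for both roles on both platforms at every truth (and
#' injected false-positive) site.
#'
#' @param config A [sim_config()].
#' @param reference Output of [simulate_reference()] (list with `reference`).
#' @param dir Optional directory to write one VCF per (role, platform,
#'   caller) plus `support.tsv` and `truth_snvs.tsv`.
#' @return List with `calls` (variant-call data.frame), `support` (pileup
#'   table: chrom, pos, ref, alt, sample_role, platform, depth, alt_reads),
#'   `truth` (chrom, pos, ref, alt, status, signature, cluster_id,
#'   true_maf_tumor, true_maf_normal), and `manifest` (per written VCF:
#'   path, sample_role, platform, caller) when `dir` is given.
#' @export
simulate_callsets <- function(config, reference, dir = NULL) {
  set.seed(child_seed(config$seed, "callsets"))
  seq_chr <- as.character(reference$reference[[1]])
  L <- nchar(seq_chr)
  tri_idx <- trinuc_index(seq_chr)   # index i = context at position i + 1

  # positions (of the center base) by pyrimidine-collapsed trinucleotide
  tri_labels <- trinuc_from_index(seq_len(64L))
  collapsed <- collapse_trinuc(tri_labels)
  pos_by_tri <- split(seq_along(tri_idx) + 1L, collapsed[tri_idx])

  mix <- config$signature_mixture
  catalog <- config$catalog[, names(mix), drop = FALSE]
  channels <- context_channels()

  draw_snvs <- function(n, region = NULL, cluster_id = NA_integer_) {
    if (n == 0L) return(NULL)
    sig <- sample(names(mix), n, replace = TRUE, prob = mix)
    chan <- vapply(sig, function(s)
      sample(channels, 1L, prob = catalog[, s]), character(1))
    parts <- lapply(chan, channel_parts)
    pos <- integer(n); ref <- character(n); alt <- character(n)
    for (i in seq_len(n)) {
      cand <- pos_by_tri[[parts[[i]]$trinuc]]
      if (!is.null(region)) {
        cand <- cand[cand >= region[1] & cand <= region[2]]
      }
      cand <- setdiff(cand, used_pos)
      if (length(cand) == 0L) {
        stop_named("crossvar_packing_error",
                   "no unused reference site with context %s%s",
                   parts[[i]]$trinuc,
                   if (is.null(region)) "" else " in cluster span")
      }
      p <- if (length(cand) == 1L) cand else sample(cand, 1L)
      used_pos <<- c(used_pos, p)
      fwd_ref <- substr(seq_chr, p, p)
      if (fwd_ref == parts[[i]]$ref) {
        ref[i] <- parts[[i]]$ref; alt[i] <- parts[[i]]$alt
      } else {
        ref[i] <- comp_base(parts[[i]]$ref); alt[i] <- comp_base(parts[[i]]$alt)
      }
      pos[i] <- p
    }
    data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt,
               signature = sig, cluster_id = cluster_id,
               stringsAsFactors = FALSE)
  }

  used_pos <- integer(0)
  somatic <- draw_snvs(config$n_somatic_snvs)
  for (k in seq_along(config$planted_clusters)) {
    cl <- config$planted_clusters[[k]]
    region <- c(max(2L, cl$position),
                min(L - 1L, cl$position + cl$span_bp - 1L))
    somatic <- rbind(somatic, draw_snvs(cl$n_snvs, region, k))
  }
  n_som <- if (is.null(somatic)) 0L else nrow(somatic)

  germline <- NULL
  if (config$n_germline_snvs > 0L) {
    gpos <- sample(setdiff(2:(L - 1L), used_pos), config$n_germline_snvs)
    used_pos <- c(used_pos, gpos)
    gref <- substring(seq_chr, gpos, gpos)
    galt <- vapply(gref, function(r) sample(setdiff(BASES, r), 1L),
                   character(1))
    germline <- data.frame(chrom = "chr1", pos = gpos, ref = gref,
                           alt = galt, signature = NA_character_,
                           cluster_id = NA_integer_, stringsAsFactors = FALSE)
  }

  # true MAFs
  maf_somatic <- function(n) {
    m <- config$purity / 2
    if (is.infinite(config$maf_concentration)) return(rep(m, n))
    rbeta(n, m * config$maf_concentration,
          (1 - m) * config$maf_concentration)
  }
  truth <- rbind(
    if (n_som) cbind(somatic, status = "somatic",
                     true_maf_tumor = maf_somatic(n_som),
                     true_maf_normal = 0),
    if (!is.null(germline)) {
      hom <- runif(nrow(germline)) < 0.3
      cbind(germline, status = "germline",
            true_maf_tumor = ifelse(hom, 1, 0.5),
            true_maf_normal = ifelse(hom, 1, 0.5))
    })
  truth <- truth[order(truth$pos), , drop = FALSE]
  rownames(truth) <- NULL

  # platform-private false positives (tumor-only calls with no true variant)
  fp <- NULL
  for (pf in PLATFORMS) {
    nfp <- config$fp_private[[pf]] %||% 0L
    if (nfp > 0L) {
      fpos <- sample(setdiff(2:(L - 1L), c(used_pos,
                                           if (!is.null(fp)) fp$pos)), nfp)
      fref <- substring(seq_chr, fpos, fpos)
      falt <- vapply(fref, function(r) sample(setdiff(BASES, r), 1L),
                     character(1))
      fp <- rbind(fp, data.frame(chrom = "chr1", pos = fpos, ref = fref,
                                 alt = falt, platform = pf,
                                 stringsAsFactors = FALSE))
    }
  }

  draw_support <- function(maf, platform, n) {
    depth <- pmax(4L, rpois(n, config$mean_depth[[platform]]))
    alt_reads <- if (config$read_noise) rbinom(n, depth, maf)
                 else as.integer(round(depth * maf))
    data.frame(depth = depth, alt_reads = alt_reads)
  }

  support <- NULL; calls <- NULL
  for (role in SAMPLE_ROLES) {
    maf_col <- if (role == "tumor") truth$true_maf_tumor
               else truth$true_maf_normal
    for (pf in PLATFORMS) {
      sup <- draw_support(maf_col, pf, nrow(truth))
      support <- rbind(support, data.frame(
        chrom = truth$chrom, pos = truth$pos, ref = truth$ref,
        alt = truth$alt, sample_role = role, platform = pf, sup,
        stringsAsFactors = FALSE))
      callable <- if (role == "tumor") rep(TRUE, nrow(truth))
                  else truth$status == "germline"
      sens <- config$platform_sensitivity[[pf]]
      for (cl in names(sens)) {
        called <- callable & sup$alt_reads > 0L &
          runif(nrow(truth)) < sens[[cl]]
        if (any(called)) {
          calls <- rbind(calls, data.frame(
            chrom = truth$chrom[called], pos = truth$pos[called],
            ref = truth$ref[called], alt = truth$alt[called],
            sample_role = role, platform = pf, caller = cl,
            depth = sup$depth[called], alt_reads = sup$alt_reads[called],
            stringsAsFactors = FALSE))
        }
      }
    }
  }

  if (!is.null(fp)) {
    for (i in seq_len(nrow(fp))) {
      pf <- fp$platform[i]
      sup <- draw_support(0.25, pf, 1L)
      sup$alt_reads <- max(sup$alt_reads, as.integer(0.2 * sup$depth))
      for (cl in names(config$platform_sensitivity[[pf]])) {
        calls <- rbind(calls, data.frame(
          chrom = fp$chrom[i], pos = fp$pos[i], ref = fp$ref[i],
          alt = fp$alt[i], sample_role = "tumor", platform = pf,
          caller = cl, depth = sup$depth, alt_reads = sup$alt_reads,
          stringsAsFactors = FALSE))
      }
      # the other platform shows no support at a false-positive site
      other <- setdiff(PLATFORMS, pf)
      for (role in SAMPLE_ROLES) {
        for (p2 in c(pf, other)) {
          d <- pmax(4L, rpois(1L, config$mean_depth[[p2]]))
          ar <- if (p2 == pf && role == "tumor") sup$alt_reads else 0L
          support <- rbind(support, data.frame(
            chrom = fp$chrom[i], pos = fp$pos[i], ref = fp$ref[i],
            alt = fp$alt[i], sample_role = role, platform = p2,
            depth = d, alt_reads = min(ar, d), stringsAsFactors = FALSE))
        }
      }
      truth <- rbind(truth, data.frame(
        chrom = fp$chrom[i], pos = fp$pos[i], ref = fp$ref[i],
        alt = fp$alt[i], signature = NA_character_,
        cluster_id = NA_integer_, status = "false_positive",
        true_maf_tumor = NA_real_, true_maf_normal = NA_real_,
        stringsAsFactors = FALSE))
    }
  }

  if (is.null(calls)) {
    calls <- data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        sample_role = character(0), platform = character(0),
                        caller = character(0), depth = integer(0),
                        alt_reads = integer(0), stringsAsFactors = FALSE)
  }
  calls <- variant_calls(calls$chrom, calls$pos, calls$ref, calls$alt,
                         calls$sample_role, calls$platform, calls$caller,
                         calls$depth, calls$alt_reads)
  out <- list(calls = calls, support = support, truth = truth)

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    manifest <- NULL
    grp <- unique(calls[, c("sample_role", "platform", "caller")])
    for (i in seq_len(nrow(grp))) {
      sel <- calls$sample_role == grp$sample_role[i] &
        calls$platform == grp$platform[i] & calls$caller == grp$caller[i]
      p <- file.path(dir, sprintf("%s_%s_%s.vcf", grp$sample_role[i],
                                  grp$platform[i], grp$caller[i]))
      write_callset_vcf(calls[sel, , drop = FALSE], p)
      manifest <- rbind(manifest, data.frame(
        path = p, sample_role = grp$sample_role[i],
        platform = grp$platform[i], caller = grp$caller[i],
        stringsAsFactors = FALSE))
    }
    write.table(support, file.path(dir, "support.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(truth, file.path(dir, "truth_snvs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    out$manifest <- manifest
  }
  out
}

#' Write a single-sample call set as VCF 4.2 (FORMAT GT:AD:DP)
#'
#' @param calls Variant-call data.frame for one (role, platform, caller).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_callset_vcf <- function(calls, path) {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMPLE")
  lines <- hdr
  if (nrow(calls) > 0L) {
    v <- calls[order(calls$chrom, calls$pos, calls$ref, calls$alt), ,
               drop = FALSE]
    lines <- c(lines, sprintf(
      "%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:AD:DP\t0/1:%d,%d:%d",
      v$chrom, v$pos, v$ref, v$alt, v$depth - v$alt_reads, v$alt_reads,
      v$depth))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a population-panel variant load
#'
#' Per-sample, per-gene coding non-synonymous variant counts are Poisson
#' with rate `panel_rate_per_bp * exonic_length * multiplier`; low-
#' multiplier genes are the planted "conserved" genes.
#'
#' @param config A [sim_config()].
#' @param exons Gene model data.frame from [simulate_reference()].
#' @param dir Optional directory for `panel_counts.tsv` (gene, sample,
#'   count) and `panel_truth.tsv` (gene, multiplier).
#' @param write_vcf If `TRUE`, also place each panel variant at a random
#'   exonic position and write `panel.vcf` (INFO keys `PSAMPLE`, `FCLASS`).
#' @return List with `counts` (long data.frame gene/sample/count),
#'   `multipliers` (named numeric truth), and any written paths.
#' @export
simulate_panel <- function(config, exons, dir = NULL, write_vcf = FALSE) {
  set.seed(child_seed(config$seed, "panel"))
  genes <- unique(exons$gene)
  n_g <- length(genes)
  assert_that(n_g > 0L, "gene model is empty")
  glen <- vapply(genes, function(g) {
    e <- exons[exons$gene == g, , drop = FALSE]
    sum(IRanges::width(IRanges::reduce(IRanges::IRanges(e$start, e$end))))
  }, numeric(1))
  mult <- config$gene_rate_multipliers
  if (is.null(mult)) {
    mult <- stats::rgamma(n_g, shape = 1.5, rate = 1.5)
    mult[sample(n_g, max(1L, n_g %/% 10L))] <- 0.003  # planted conserved
  }
  assert_that(length(mult) == n_g,
              "need one rate multiplier per gene (%d)", n_g)
  names(mult) <- genes
  S <- config$panel_samples
  lambda <- config$panel_rate_per_bp * glen * mult
  counts <- data.frame(
    gene = rep(genes, each = S),
    sample = rep(sprintf("S%04d", seq_len(S)), times = n_g),
    count = rpois(n_g * S, rep(lambda, each = S)),
    stringsAsFactors = FALSE)
  out <- list(counts = counts, multipliers = mult)
  if (isTRUE(write_vcf)) {
    rows <- counts[counts$count > 0L, , drop = FALSE]
    vlines <- character(0)
    for (i in seq_len(nrow(rows))) {
      e <- exons[exons$gene == rows$gene[i], , drop = FALSE]
      epos <- unlist(Map(seq, e$start, e$end))
      p <- sample(epos, rows$count[i], replace = TRUE)
      vlines <- c(vlines, sprintf(
        "chr1\t%d\t.\tN\tA\t.\tPASS\tPSAMPLE=%s;FCLASS=nonsynonymous",
        p, rows$sample[i]))
    }
    hdr <- c("##fileformat=VCFv4.2",
             '##INFO=<ID=PSAMPLE,Number=1,Type=String,Description="Panel sample">',
             '##INFO=<ID=FCLASS,Number=1,Type=String,Description="Functional class">',
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    out$vcf_lines <- c(hdr, vlines)
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$counts_path <- file.path(dir, "panel_counts.tsv")
    write.table(counts, out$counts_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(data.frame(gene = genes, multiplier = mult),
                file.path(dir, "panel_truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (isTRUE(write_vcf)) {
      out$vcf_path <- file.path(dir, "panel.vcf")
      writeLines(out$vcf_lines, out$vcf_path)
    }
  }
  out
}

#' Simulate structural-variant inputs
#'
#' Plants germline and somatic SVs of each type. Germline interval SVs and
#' translocations are emitted into both the tumor and the control call set;
#' somatic ones only into the tumor set. De novo insertion contigs carry a
#' control-read coverage profile: germline contigs are covered (depth >= 1)
#' at >= 90% of positions, somatic ones below that.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory for `sv_tumor.tsv`, `sv_control.tsv`,
#'   `contigs.fa`, `contig_coverage.tsv`, `truth_svs.tsv`.
#' @param jitter_bp Uniform +/- jitter applied to control-set breakpoint
#'   copies of germline SVs (default 0 = exact coordinates).
#' @return List with `tumor`, `control` (SV data.frames: sv_type, chrom1,
#'   start1, end1, chrom2, start2, end2, supporting_pairs,
#'   supporting_splits), `contigs` (`DNAStringSet`), `coverage` (contig_id,
#'   pos, depth), `truth` (record, sv_type, label).
#' @export
simulate_svs <- function(config, dir = NULL, jitter_bp = 0L) {
  set.seed(child_seed(config$seed, "svs"))
  L <- config$genome_length
  svc <- config$sv
  types <- c("deletion", "inversion", "tandem_duplication", "translocation")
  tumor <- NULL; control <- NULL; truth <- NULL
  rid <- 0L
  for (tp in types) {
    for (lab in c("germline", "somatic")) {
      n <- svc[[tp]][[lab]] %||% 0L
      for (i in seq_len(n)) {
        rid <- rid + 1L
        id <- sprintf("SV%03d", rid)
        if (tp == "translocation") {
          rec <- data.frame(record = id, sv_type = tp, chrom1 = "chr1",
                            start1 = sample(L, 1L), end1 = NA_integer_,
                            chrom2 = "chr2", start2 = sample(L, 1L),
                            end2 = NA_integer_, stringsAsFactors = FALSE)
          rec$end1 <- rec$start1; rec$end2 <- rec$start2
        } else {
          size <- max(6L, as.integer(runif(1L, 50, 5000)))
          s <- sample(L - size, 1L)
          rec <- data.frame(record = id, sv_type = tp, chrom1 = "chr1",
                            start1 = s, end1 = s + size, chrom2 = NA,
                            start2 = NA_integer_, end2 = NA_integer_,
                            stringsAsFactors = FALSE)
        }
        rec$supporting_pairs <- 3L + rpois(1L, 5)
        rec$supporting_splits <- 2L + rpois(1L, 3)
        rec$sample_role <- "tumor"
        tumor <- rbind(tumor, rec)
        if (lab == "germline") {
          crec <- rec
          crec$sample_role <- "control"
          if (jitter_bp > 0L) {
            j <- function(x) x + sample(seq(-jitter_bp, jitter_bp), 1L)
            crec$start1 <- j(crec$start1); crec$end1 <- j(crec$end1)
            if (!is.na(crec$start2)) {
              crec$start2 <- j(crec$start2); crec$end2 <- j(crec$end2)
            }
          }
          control <- rbind(control, crec)
        }
        truth <- rbind(truth, data.frame(record = id, sv_type = tp,
                                         label = lab,
                                         stringsAsFactors = FALSE))
      }
    }
  }

  # de novo insertion contigs with control coverage profiles
  n_g <- svc$n_germline_ins %||% 0L
  n_s <- svc$n_somatic_ins %||% 0L
  contigs <- character(0); coverage <- NULL
  for (i in seq_len(n_g + n_s)) {
    lab <- if (i <= n_g) "germline" else "somatic"
    rid <- rid + 1L
    id <- sprintf("contig%03d", i)
    clen <- sample(200:500, 1L)
    contigs[id] <- paste(sample(BASES, clen, replace = TRUE), collapse = "")
    frac <- if (lab == "germline") runif(1L, 0.92, 1.0) else runif(1L, 0.3, 0.85)
    covered <- sample(clen, round(frac * clen))
    depth <- integer(clen)
    depth[covered] <- 1L + rpois(length(covered), 4)
    coverage <- rbind(coverage, data.frame(contig_id = id, pos = seq_len(clen),
                                           depth = depth,
                                           stringsAsFactors = FALSE))
    truth <- rbind(truth, data.frame(record = id, sv_type = "insertion",
                                     label = lab, stringsAsFactors = FALSE))
  }
  contigs <- Biostrings::DNAStringSet(contigs)

  out <- list(tumor = tumor, control = control, contigs = contigs,
              coverage = coverage, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write.table(tumor, file.path(dir, "sv_tumor.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(control, file.path(dir, "sv_control.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    Biostrings::writeXStringSet(contigs, file.path(dir, "contigs.fa"))
    write.table(coverage, file.path(dir, "contig_coverage.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(truth, file.path(dir, "truth_svs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  out
}
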