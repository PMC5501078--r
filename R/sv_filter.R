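# Structural-variant filtering: split-read quality criteria, somatic
# classification against the control call set, the de novo insertion
# germline-exclusion rule, and gene-context annotation.

#' Filter split reads by quality and alignment criteria
#'
#' A read passes when it has at least `min_q_positions` base calls with
#' quality >= `q`, at most `max_parts` alignment parts, and a total of at
#' least `min_mapped` mapped bases across its parts.
#'
#' @param reads List of split-read records: each a list with
#'   `base_qualities` (integer vector), `alignment_parts` (list of
#'   `(target, start, end)`), `mapped_bases` (total mapped bases; computed
#'   from the parts when absent).
#' @param q Quality threshold (default 35).
#' @param min_q_positions Minimum number of positions at or above `q`
#'   (default 95).
#' @param max_parts Maximum alignment parts (default 2).
#' @param min_mapped Minimum summed mapped bases (default 92).
#' @return The passing subset of `reads`.
#' @export
filter_split_reads <- function(reads, q = 35L, min_q_positions = 95L,
                               max_parts = 2L, min_mapped = 92L) {
  keep <- vapply(reads, function(r) {
    mapped <- r$mapped_bases %||% sum(vapply(r$alignment_parts, function(p)
      abs(p$end - p$start) + 1L, numeric(1)))
    sum(r$base_qualities >= q) >= min_q_positions &&
      length(r$alignment_parts) <= max_parts &&
      mapped >= min_mapped
  }, logical(1))
  reads[keep]
}

#' Classify de novo insertion contigs as germline or somatic
#'
#' A tumor-assembled contig is germline (and excluded from the somatic
#' candidates) when control-sample reads cover at least
#' `germline_coverage_fraction` of its positions (depth >= 1); the bound is
#' inclusive, so 90 covered positions of 100 are germline under the
#' default.
#'
#' @param coverage data.frame `contig_id, pos, depth` of control-read
#'   coverage along each contig (every position present).
#' @param germline_coverage_fraction Inclusive coverage-fraction bound
#'   (default 0.90).
#' @return data.frame `contig_id, length, covered_fraction, label`
#'   (`"germline"` or `"somatic"`).
#' @export
classify_insertions <- function(coverage,
                                germline_coverage_fraction = 0.90) {
  ids <- unique(coverage$contig_id)
  rows <- lapply(ids, function(id) {
    cov <- coverage[coverage$contig_id == id, , drop = FALSE]
    len <- nrow(cov)
    frac <- sum(cov$depth >= 1L) / len
    data.frame(contig_id = id, length = len, covered_fraction = frac,
               label = if (frac >= germline_coverage_fraction) "germline"
                       else "somatic",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

sv_match <- function(a, b, overlap, slop) {
  if (a$sv_type != b$sv_type) return(FALSE)
  if (a$sv_type == "translocation") {
    return(a$chrom1 == b$chrom1 && a$chrom2 == b$chrom2 &&
             abs(a$start1 - b$start1) <= slop &&
             abs(a$start2 - b$start2) <= slop)
  }
  if (a$chrom1 != b$chrom1) return(FALSE)
  ov <- min(a$end1, b$end1) - max(a$start1, b$start1) + 1L
  if (ov <= 0L) return(FALSE)
  wa <- a$end1 - a$start1 + 1L
  wb <- b$end1 - b$start1 + 1L
  ov / wa >= overlap && ov / wb >= overlap
}

#' Somatic classification of structural variants
#'
#' A quality-filtered tumor SV is somatic when no control SV of the same
#' type matches it: interval types (deletion, inversion, tandem
#' duplication) match by reciprocal overlap >= `overlap`; translocations
#' match when both breakpoints agree within `breakpoint_slop`. Mutually
#' overlapping somatic SVs of one type are merged into clusters for the
#' "non-overlapping" count.
#'
#' @param tumor,control SV data.frames (`record, sv_type, chrom1, start1,
#'   end1, chrom2, start2, end2`, plus support columns).
#' @param overlap Reciprocal-overlap fraction (default 0.5).
#' @param breakpoint_slop Translocation breakpoint tolerance in bp
#'   (default 100).
#' @return List: `somatic` (the somatic subset of `tumor`),
#'   `non_overlapping` (named per-type cluster counts),
#'   `somatic_counts` (named per-type somatic counts).
#' @export
somatic_svs <- function(tumor, control, overlap = 0.5,
                        breakpoint_slop = 100L) {
  if (is.null(tumor) || nrow(tumor) == 0L) {
    return(list(somatic = tumor, non_overlapping = integer(0),
                somatic_counts = integer(0)))
  }
  ctl <- if (is.null(control)) tumor[0, , drop = FALSE] else control
  is_somatic <- vapply(seq_len(nrow(tumor)), function(i) {
    a <- tumor[i, ]
    same_type <- ctl[ctl$sv_type == a$sv_type, , drop = FALSE]
    if (nrow(same_type) == 0L) return(TRUE)
    !any(vapply(seq_len(nrow(same_type)), function(j)
      sv_match(a, same_type[j, ], overlap, breakpoint_slop), logical(1)))
  }, logical(1))
  som <- tumor[is_somatic, , drop = FALSE]
  types <- sort(unique(som$sv_type))
  nonov <- setNames(integer(length(types)), types)
  for (tp in types) {
    s <- som[som$sv_type == tp, , drop = FALSE]
    if (tp == "translocation") {
      nonov[tp] <- nrow(s)  # point breakpoints: every event is its own cluster
      next
    }
    n_clusters <- 0L
    for (ch in unique(s$chrom1)) {
      sc <- s[s$chrom1 == ch, , drop = FALSE]
      sc <- sc[order(sc$start1), , drop = FALSE]
      cur_end <- -Inf
      for (i in seq_len(nrow(sc))) {
        if (sc$start1[i] > cur_end) {
          n_clusters <- n_clusters + 1L
          cur_end <- sc$end1[i]
        } else {
          cur_end <- max(cur_end, sc$end1[i])
        }
      }
    }
    nonov[tp] <- n_clusters
  }
  list(somatic = som, non_overlapping = nonov,
       somatic_counts = setNames(as.integer(table(som$sv_type)[types]),
                                 types))
}

#' Annotate SVs with gene context
#'
#' Labels each SV breakpoint/interval exonic (intersects an exon), intronic
#' (inside a gene body but no exon), or intergenic, reports the nearest
#' gene with its distance, and flags events within 100 kb of a gene.
#'
#' @param svs SV data.frame (uses `chrom1, start1, end1`, and `chrom2,
#'   start2` for translocations).
#' @param exons Gene model data.frame (`gene, chrom, start, end`).
#' @param proximity_bp Proximity flag distance (default 1e5).
#' @return `svs` with added `region`, `genes`, `nearest_gene`,
#'   `gene_distance`, `near_gene` columns.
#' @export
annotate_sv_genes <- function(svs, exons, proximity_bp = 100000L) {
  ex_gr <- GenomicRanges::GRanges(exons$chrom,
                                  IRanges::IRanges(exons$start, exons$end),
                                  gene = exons$gene)
  gene_df <- do.call(rbind, lapply(split(exons, exons$gene), function(e)
    data.frame(gene = e$gene[1], chrom = e$chrom[1], start = min(e$start),
               end = max(e$end), stringsAsFactors = FALSE)))
  gene_gr <- GenomicRanges::GRanges(gene_df$chrom,
                                    IRanges::IRanges(gene_df$start,
                                                     gene_df$end),
                                    gene = gene_df$gene)
  n <- nrow(svs)
  region <- character(n); genes <- character(n)
  nearest_gene <- character(n); gene_distance <- integer(n)
  for (i in seq_len(n)) {
    end1 <- if (is.na(svs$end1[i])) svs$start1[i] else svs$end1[i]
    loci <- GenomicRanges::GRanges(
      svs$chrom1[i], IRanges::IRanges(svs$start1[i], end1))
    if (identical(svs$sv_type[i], "translocation") &&
        !is.na(svs$start2[i])) {
      loci <- c(loci, GenomicRanges::GRanges(
        svs$chrom2[i], IRanges::IRanges(svs$start2[i], svs$start2[i])))
    }
    ex_hit <- GenomicRanges::findOverlaps(loci, ex_gr)
    gn_hit <- GenomicRanges::findOverlaps(loci, gene_gr)
    if (length(ex_hit) > 0L) {
      region[i] <- "exonic"
      genes[i] <- paste(sort(unique(
        ex_gr$gene[S4Vectors::subjectHits(ex_hit)])), collapse = ",")
    } else if (length(gn_hit) > 0L) {
      region[i] <- "intronic"
      genes[i] <- paste(sort(unique(
        gene_gr$gene[S4Vectors::subjectHits(gn_hit)])), collapse = ",")
    } else {
      region[i] <- "intergenic"
      genes[i] <- ""
    }
    dd <- GenomicRanges::distanceToNearest(loci, gene_gr)
    if (length(dd) > 0L) {
      best <- which.min(S4Vectors::mcols(dd)$distance)
      nearest_gene[i] <- gene_gr$gene[S4Vectors::subjectHits(dd)[best]]
      gene_distance[i] <- S4Vectors::mcols(dd)$distance[best]
    } else {
      nearest_gene[i] <- NA_character_
      gene_distance[i] <- NA_integer_
    }
  }
  svs$region <- region
  svs$genes <- genes
  svs$nearest_gene <- nearest_gene
  svs$gene_distance <- gene_distance
  svs$near_gene <- !is.na(gene_distance) & gene_distance < proximity_bp
  svs
}
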