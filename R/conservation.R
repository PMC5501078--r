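# Exonic gene conservation score (ECS): the exonic variant rate of a gene
# in a population panel divided by the panel-wide average exonic rate.
#
#   ECS_g = (V_g * L_tot) / (L_g * V_avg * S)
#
# with V_g the panel-wide coding non-synonymous variant count in gene g,
# L_g the gene's exonic (union) length, L_tot the total exonic length over
# all modeled genes, V_avg the mean per-sample total exonic variant count,
# and S the number of panel samples. Smaller ECS means higher conservation;
# genes with ECS < 0.01 are defined as conserved.

exonic_lengths <- function(exons) {
  genes <- unique(exons$gene)
  setNames(vapply(genes, function(g) {
    e <- exons[exons$gene == g, , drop = FALSE]
    sum(IRanges::width(IRanges::reduce(IRanges::IRanges(e$start, e$end))))
  }, numeric(1)), genes)
}

#' Build per-gene panel statistics
#'
#' Accepts either a long count table (columns `gene, sample, count`; e.g.
#' the TSV written by [simulate_panel()]) or a panel VCF whose records
#' carry `PSAMPLE` and `FCLASS` INFO keys; VCF variants are restricted to
#' coding non-synonymous classes, assigned to genes by position within the
#' exon union (a variant inside two overlapping genes counts for both),
#' and variants outside all exons are ignored (counted in `n_outside`).
#'
#' @param panel data.frame, TSV path, or VCF path (`*.vcf`).
#' @param exons Gene model data.frame (`gene, chrom, start, end`).
#' @param n_samples Panel size `S`; defaults to the number of distinct
#'   samples observed in the input (supply explicitly if some samples have
#'   zero variants).
#' @param avg_over `"samples"` (default): `V_avg` is the mean per-sample
#'   total exonic variant count. `"genes"`: mean per-gene panel count
#'   (alternative reading, changes only the overall scale).
#' @return Object of class `panel_stats`.
#' @export
build_panel_stats <- function(panel, exons, n_samples = NULL,
                              avg_over = c("samples", "genes")) {
  avg_over <- match.arg(avg_over)
  assert_that(nrow(exons) > 0L, "gene model is empty")
  n_outside <- 0L
  if (is.character(panel) && length(panel) == 1L) {
    if (grepl("\\.vcf$", panel)) {
      parsed <- panel_counts_from_vcf(panel, exons)
      counts <- parsed$counts
      n_outside <- parsed$n_outside
    } else {
      counts <- read.table(panel, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
    }
  } else {
    counts <- panel
  }
  assert_that(all(c("gene", "sample", "count") %in% names(counts)),
              "panel counts need columns gene, sample, count")
  glen <- exonic_lengths(exons)
  genes <- names(glen)
  vg <- tapply(counts$count, factor(counts$gene, levels = genes), sum,
               default = 0)
  vg <- setNames(as.numeric(vg), genes)
  per_sample <- tapply(counts$count, counts$sample, sum)
  S <- n_samples %||% length(per_sample)
  v_avg <- if (avg_over == "samples") sum(counts$count) / S else mean(vg)
  structure(list(n_samples = S, per_gene_variants = vg,
                 gene_length = glen, total_exonic_length = sum(glen),
                 avg_total_exonic_variants = v_avg, avg_over = avg_over,
                 n_outside = n_outside),
            class = "panel_stats")
}

panel_counts_from_vcf <- function(path, exons) {
  vcf <- VariantAnnotation::readVcf(path)
  info <- VariantAnnotation::info(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  keep <- as.character(info$FCLASS) %in% c("nonsynonymous", "stopgain")
  chrom <- as.character(GenomicRanges::seqnames(rr))[keep]
  pos <- GenomicRanges::start(rr)[keep]
  smp <- as.character(info$PSAMPLE)[keep]
  ex_gr <- GenomicRanges::GRanges(exons$chrom,
                                  IRanges::IRanges(exons$start, exons$end),
                                  gene = exons$gene)
  v_gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  hits <- GenomicRanges::findOverlaps(v_gr, ex_gr)
  qh <- S4Vectors::queryHits(hits)
  gh <- ex_gr$gene[S4Vectors::subjectHits(hits)]
  assigned <- unique(data.frame(i = qh, gene = gh, stringsAsFactors = FALSE))
  n_outside <- length(pos) - length(unique(assigned$i))
  tab <- table(gene = assigned$gene, sample = smp[assigned$i])
  counts <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(counts) <- c("gene", "sample", "count")
  list(counts = counts[counts$count > 0L, , drop = FALSE],
       n_outside = n_outside)
}

#' @export
print.panel_stats <- function(x, ...) {
  cat(sprintf(paste0("Panel statistics: %d samples, %d genes, %d bp exonic, ",
                     "mean %.2f exonic variants/sample\n"),
              x$n_samples, length(x$gene_length), x$total_exonic_length,
              x$avg_total_exonic_variants))
  invisible(x)
}

#' Exonic gene conservation score
#'
#' `ECS = (V_g * L_tot) / (L_g * V_avg * S)`; 0 for a gene with no panel
#' variants (maximally conserved), 1 for a gene whose per-bp variant
#' density equals the panel-wide average.
#'
#' @param stats A [build_panel_stats()] object.
#' @param gene Gene symbol(s); default all genes in the model.
#' @return Named numeric score(s) >= 0.
#' @export
ecs <- function(stats, gene = names(stats$gene_length)) {
  assert_that(all(gene %in% names(stats$gene_length)),
              "unknown gene(s): %s",
              paste(setdiff(gene, names(stats$gene_length)), collapse = ", "))
  lg <- stats$gene_length[gene]
  if (stats$avg_total_exonic_variants <= 0 || stats$n_samples <= 0 ||
      any(lg <= 0)) {
    stop_named("crossvar_ecs_degenerate",
               "ECS denominator is zero (V_avg, S and L_g must be positive)")
  }
  (stats$per_gene_variants[gene] * stats$total_exonic_length) /
    (lg * stats$avg_total_exonic_variants * stats$n_samples)
}

#' Conserved gene set
#'
#' @param stats A [build_panel_stats()] object.
#' @param threshold Strict upper ECS bound (default 0.01).
#' @return Sorted character vector of genes with `ECS < threshold`.
#' @export
conserved_genes <- function(stats, threshold = 0.01) {
  scores <- ecs(stats)
  sort(names(scores)[scores < threshold])
}

#' Per-gene ECS table
#'
#' @param stats A [build_panel_stats()] object.
#' @param threshold Conservation threshold passed to [conserved_genes()].
#' @param path Optional TSV output path.
#' @return data.frame `gene, exonic_length, panel_variants, ecs, conserved`.
#' @export
ecs_table <- function(stats, threshold = 0.01, path = NULL) {
  scores <- ecs(stats)
  out <- data.frame(gene = names(scores),
                    exonic_length = as.integer(stats$gene_length),
                    panel_variants = as.integer(stats$per_gene_variants),
                    ecs = as.numeric(scores),
                    conserved = as.numeric(scores) < threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(out$ecs, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
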