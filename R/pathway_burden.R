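# GO-term variant burden: per-term load of damaging variants in a tumor
# compared against the maximum per-sample load in a population panel.

#' Per-term load of damaging variants
#'
#' Only variants flagged damaging contribute; a variant contributes to
#' every term its gene maps to, and `gene_count` counts distinct genes.
#'
#' @param variants data.frame with `gene` and logical `damaging`.
#' @param term_map data.frame `gene, term` (one row per membership).
#' @return data.frame `term, gene_count, variant_count`.
#' @export
term_load <- function(variants, term_map) {
  assert_that(nrow(term_map) > 0L, "gene-to-term map is empty")
  v <- variants[isTRUE_vec(variants$damaging), , drop = FALSE]
  m <- merge(v[, "gene", drop = FALSE], term_map, by = "gene")
  if (nrow(m) == 0L) {
    return(data.frame(term = character(0), gene_count = integer(0),
                      variant_count = integer(0), stringsAsFactors = FALSE))
  }
  vc <- tapply(m$gene, m$term, length)
  gc <- tapply(m$gene, m$term, function(g) length(unique(g)))
  out <- data.frame(term = names(vc), gene_count = as.integer(gc[names(vc)]),
                    variant_count = as.integer(vc), stringsAsFactors = FALSE)
  out[order(out$term), , drop = FALSE]
}

#' Compare tumor term loads against the panel per-sample maximum
#'
#' A term is enriched (by genes or by variants) when the tumor count is
#' strictly greater than the maximum count over individual panel samples
#' (never the pooled panel). Terms absent from every panel sample have
#' panel maximum 0.
#'
#' @param tumor_loads Output of [term_load()] for the tumor.
#' @param panel_loads Per-sample panel loads: data.frame `sample, term,
#'   gene_count, variant_count` (e.g. [term_load()] per sample, row-bound
#'   with a `sample` column).
#' @param path Optional TSV output path (sorted by tumor variant count).
#' @return data.frame of term statistics: `term, tumor_gene_count,
#'   tumor_variant_count, panel_max_gene_count, panel_max_variant_count,
#'   enriched_by_genes, enriched_by_variants`.
#' @export
compare_to_panel <- function(tumor_loads, panel_loads, path = NULL) {
  terms <- sort(unique(c(tumor_loads$term, panel_loads$term)))
  pmaxg <- setNames(integer(length(terms)), terms)
  pmaxv <- setNames(integer(length(terms)), terms)
  if (nrow(panel_loads) > 0L) {
    mg <- tapply(panel_loads$gene_count, panel_loads$term, max)
    mv <- tapply(panel_loads$variant_count, panel_loads$term, max)
    pmaxg[names(mg)] <- as.integer(mg)
    pmaxv[names(mv)] <- as.integer(mv)
  }
  tg <- setNames(integer(length(terms)), terms)
  tv <- setNames(integer(length(terms)), terms)
  tg[tumor_loads$term] <- tumor_loads$gene_count
  tv[tumor_loads$term] <- tumor_loads$variant_count
  out <- data.frame(term = terms,
                    tumor_gene_count = as.integer(tg),
                    tumor_variant_count = as.integer(tv),
                    panel_max_gene_count = as.integer(pmaxg),
                    panel_max_variant_count = as.integer(pmaxv),
                    enriched_by_genes = tg > pmaxg,
                    enriched_by_variants = tv > pmaxv,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$tumor_variant_count, out$term), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
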