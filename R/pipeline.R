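# End-to-end orchestration: simulate (or load) inputs, consolidate calls,
# extract somatic variants, then run purity, spectrum/cluster, signature,
# conservation, burden and SV stages, writing per-stage artifacts and a
# machine-readable run manifest.

#' Annotate variants against a gene model
#'
#' Deterministic, seed-driven stand-in for an external functional annotator:
#' variants inside an exon are labelled `nonsynonymous` (a fixed fraction
#' `stopgain`), inside a gene body `intronic`, otherwise `intergenic`;
#' exonic variants get pseudo-random `damaging` and `conserved_position`
#' flags. `novel` is `TRUE` unless the variant appears in `known_sites`.
#'
#' @param variants Consolidated variant data.frame (`chrom, pos, ref, alt`).
#' @param exons Gene model data.frame.
#' @param seed Integer seed for the annotation flags.
#' @param p_stopgain,p_damaging,p_conserved_pos Flag probabilities among
#'   exonic variants.
#' @param known_sites Optional data.frame (`chrom, pos, ref, alt`) of known
#'   (dbSNP-like) sites.
#' @return `variants` with `gene, functional_class, damaging,
#'   conserved_position, novel` columns.
#' @export
annotate_variants <- function(variants, exons, seed = 1L,
                              p_stopgain = 0.05, p_damaging = 0.4,
                              p_conserved_pos = 0.2, known_sites = NULL) {
  set.seed(child_seed(seed, "annotate"))
  n <- nrow(variants)
  gene <- character(n); fclass <- character(n)
  if (nrow(exons) > 0L) {
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
    v_gr <- GenomicRanges::GRanges(variants$chrom,
                                   IRanges::IRanges(variants$pos,
                                                    variants$pos))
    ex_hit <- GenomicRanges::findOverlaps(v_gr, ex_gr, select = "first")
    gn_hit <- GenomicRanges::findOverlaps(v_gr, gene_gr, select = "first")
    for (i in seq_len(n)) {
      if (!is.na(ex_hit[i])) {
        gene[i] <- ex_gr$gene[ex_hit[i]]
        fclass[i] <- if (runif(1) < p_stopgain) "stopgain"
                     else "nonsynonymous"
      } else if (!is.na(gn_hit[i])) {
        gene[i] <- gene_gr$gene[gn_hit[i]]
        fclass[i] <- "intronic"
      } else {
        gene[i] <- ""
        fclass[i] <- "intergenic"
      }
    }
  } else {
    gene <- rep("", n)
    fclass <- rep("intergenic", n)
  }
  exonic <- fclass %in% c("nonsynonymous", "stopgain")
  variants$gene <- gene
  variants$functional_class <- fclass
  variants$damaging <- exonic & runif(n) < p_damaging
  variants$conserved_position <- exonic & runif(n) < p_conserved_pos
  novel <- rep(TRUE, n)
  if (!is.null(known_sites) && nrow(known_sites) > 0L) {
    novel <- !(variant_key(variants) %in% variant_key(known_sites))
  }
  variants$novel <- novel
  variants
}

#' Run the full interpretation pipeline on synthetic inputs
#'
#' Simulates the reference, call sets, panel and structural variants from
#' `config`, then runs the stages in dependency order (consolidate,
#' somatic, then purity / spectrum / clusters / signatures / candidates;
#' ECS and pathway burden from the panel; SV filtering independently),
#' writing per-stage artifacts and a run manifest into `out_dir`.
#' Re-running with the same configuration reproduces all outputs exactly.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created).
#' @param stages Character subset of
#'   `c("consolidate", "purity", "spectrum", "signatures", "ecs",
#'   "burden", "sv")`; `"consolidate"` is implied by any stage that needs
#'   somatic variants.
#' @return Invisible list of stage results (also serialized under
#'   `out_dir`).
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("consolidate", "purity", "spectrum",
                                    "signatures", "ecs", "burden", "sv")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  log_stage <- function(fmt, ...) {
    message(sprintf("[crossvar %7.2fs] %s", proc.time()[["elapsed"]] - t0,
                    sprintf(fmt, ...)))
  }
  results <- list(config = config)

  log_stage("simulate: reference, call sets, panel, SVs (seed %d)",
            config$seed)
  ref <- simulate_reference(config, dir = file.path(out_dir, "inputs"))
  sim <- simulate_callsets(config, ref, dir = file.path(out_dir, "inputs"))
  panel <- simulate_panel(config, ref$exons,
                          dir = file.path(out_dir, "inputs"))
  svs <- simulate_svs(config, dir = file.path(out_dir, "inputs"))
  results$truth <- sim$truth

  needs_somatic <- any(c("consolidate", "purity", "spectrum", "signatures",
                         "burden") %in% stages)
  somatic_set <- NULL
  if (needs_somatic) {
    log_stage("consolidate: tiering and somatic extraction")
    cons <- classify_tier(sim$calls, support = sim$support)
    tumor <- cons[cons$sample_role == "tumor", , drop = FALSE]
    normal <- cons[cons$sample_role == "normal", , drop = FALSE]
    tumor <- extract_somatic(tumor, normal, support = sim$support)
    tumor <- annotate_variants(tumor, ref$exons, seed = config$seed)
    somatic_set <- tumor[isTRUE_vec(tumor$somatic), , drop = FALSE]
    write_consolidated(tumor, file.path(out_dir, "consolidated.vcf"))
    results$consolidated <- tumor
  }

  stats <- NULL
  if ("ecs" %in% stages) {
    log_stage("ecs: panel statistics and conservation scores")
    stats <- build_panel_stats(panel$counts, ref$exons,
                               n_samples = config$panel_samples)
    results$ecs <- ecs_table(stats, path = file.path(out_dir, "ecs.tsv"))
    results$conserved <- conserved_genes(stats)
  }

  if ("consolidate" %in% stages) {
    candidates <- select_candidates(somatic_set,
                                    ecs_conserved = results$conserved %||%
                                      character(0))
    results$candidates <- candidates
    results$report <- build_report(sim$calls, tumor, tumor, candidates,
                                   path = file.path(out_dir,
                                                    "filter_report.tsv"))
  }

  if ("purity" %in% stages) {
    log_stage("purity: cellularity from somatic MAFs")
    mafs <- somatic_set$maf_WGS
    results$purity <- tryCatch(
      estimate_purity(mafs),
      crossvar_insufficient_data = function(e) {
        log_stage("purity skipped: %s", conditionMessage(e)); NULL
      })
    if (!is.null(results$purity)) {
      write.table(data.frame(estimate = results$purity$estimate,
                             n_variants = results$purity$n_variants,
                             method = results$purity$method),
                  file.path(out_dir, "purity.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }

  if ("spectrum" %in% stages) {
    log_stage("spectrum: 6/96-channel spectra, rainfall, clusters")
    snvs <- somatic_set[nchar(somatic_set$ref) == 1L &
                          nchar(somatic_set$alt) == 1L, , drop = FALSE]
    spec <- build_spectrum(snvs, ref$reference)
    results$spectrum <- spec
    write.table(data.frame(class = names(spec$counts6),
                           count = as.integer(spec$counts6)),
                file.path(out_dir, "spectrum6.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(channel = names(spec$counts96),
                           count = as.integer(spec$counts96),
                           normalized = spec$normalized96),
                file.path(out_dir, "spectrum96.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    rf <- rainfall(snvs)
    write.table(rf, file.path(out_dir, "rainfall.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    results$clusters <- detect_clusters(snvs)
    write.table(results$clusters, file.path(out_dir, "clusters.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if ("signatures" %in% stages) {
    log_stage("signatures: catalog refit of the somatic spectrum")
    spec <- results$spectrum %||% build_spectrum(
      somatic_set[nchar(somatic_set$ref) == 1L &
                    nchar(somatic_set$alt) == 1L, , drop = FALSE],
      ref$reference)
    fit <- fit_exposures(spec$counts96, config$catalog)
    results$exposures <- fit
    write.table(data.frame(signature = names(fit$exposures),
                           exposure = as.numeric(fit$exposures)),
                file.path(out_dir, "exposures.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  if ("burden" %in% stages) {
    log_stage("burden: GO-term load vs panel maximum")
    # toy map: every gene belongs to one of 10 synthetic terms
    genes <- unique(ref$exons$gene)
    term_map <- data.frame(gene = genes,
                           term = sprintf("GO:%07d",
                                          seq_along(genes) %% 10L + 1L),
                           stringsAsFactors = FALSE)
    tumor_loads <- term_load(somatic_set, term_map)
    set.seed(child_seed(config$seed, "burden_panel"))
    panel_loads <- NULL
    glen <- exonic_lengths(ref$exons)
    for (s in seq_len(min(config$panel_samples, 50L))) {
      cnt <- rpois(length(genes), config$panel_rate_per_bp * glen *
                     (panel$multipliers[genes]))
      pv <- data.frame(gene = rep(genes, cnt), damaging = TRUE,
                       stringsAsFactors = FALSE)
      tl <- term_load(pv, term_map)
      if (nrow(tl)) {
        tl$sample <- sprintf("S%04d", s)
        panel_loads <- rbind(panel_loads, tl)
      }
    }
    results$burden <- compare_to_panel(
      tumor_loads, panel_loads %||% data.frame(
        sample = character(0), term = character(0), gene_count = integer(0),
        variant_count = integer(0)),
      path = file.path(out_dir, "burden.tsv"))
  }

  if ("sv" %in% stages) {
    log_stage("sv: somatic classification and insertion germline exclusion")
    som <- somatic_svs(svs$tumor, svs$control)
    results$sv <- som
    write.table(som$somatic, file.path(out_dir, "sv_somatic.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    results$insertions <- classify_insertions(svs$coverage)
    write.table(results$insertions, file.path(out_dir, "insertions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- c(
    sprintf("seed\t%d", config$seed),
    sprintf("genome_length\t%d", config$genome_length),
    sprintf("purity\t%g", config$purity),
    sprintf("n_truth_somatic\t%d", sum(sim$truth$status == "somatic")),
    sprintf("n_truth_germline\t%d", sum(sim$truth$status == "germline")),
    if (!is.null(results$consolidated)) {
      c(sprintf("n_cross_platform\t%d",
                sum(results$consolidated$tier == "cross_platform")),
        sprintf("n_somatic\t%d",
                sum(isTRUE_vec(results$consolidated$somatic))),
        sprintf("n_candidates\t%d", nrow(results$candidates %||%
                                           data.frame())))
    },
    if (!is.null(results$purity)) {
      sprintf("purity_estimate\t%.4f", results$purity$estimate)
    },
    if (!is.null(results$conserved)) {
      sprintf("n_conserved_genes\t%d", length(results$conserved))
    })
  writeLines(manifest, file.path(out_dir, "run_manifest.tsv"))
  log_stage("done: artifacts in %s", out_dir)
  invisible(results)
}
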