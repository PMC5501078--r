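# The synthetic-data generator: determinism, constraint satisfaction, and
# distributional properties of the stated world.

test_that("simulate_reference packs disjoint genes and is deterministic", {
  cfg <- sim_config(seed = 9, genome_length = 100000L, n_genes = 10L)
  ref <- simulate_reference(cfg)
  expect_equal(length(ref$reference[[1]]), 100000L)
  # gene bodies are pairwise disjoint and within bounds
  genes <- split(ref$exons, ref$exons$gene)
  spans <- t(vapply(genes, function(e) c(min(e$start), max(e$end)),
                    numeric(2)))
  spans <- spans[order(spans[, 1]), , drop = FALSE]
  expect_true(all(spans[, 1] >= 1 & spans[, 2] <= 100000))
  expect_true(all(diff(as.vector(t(spans))) > 0))
  # same seed, byte-identical FASTA
  d1 <- file.path(tempdir(), "ref1"); d2 <- file.path(tempdir(), "ref2")
  r1 <- simulate_reference(cfg, dir = d1)
  r2 <- simulate_reference(cfg, dir = d2)
  expect_identical(readLines(r1$fasta_path), readLines(r2$fasta_path))
  expect_identical(readLines(r1$bed_path), readLines(r2$bed_path))
})

test_that("n_genes = 0 gives an empty gene model and empty BED", {
  cfg <- sim_config(seed = 1, n_genes = 0L)
  d <- file.path(tempdir(), "ref0")
  ref <- simulate_reference(cfg, dir = d)
  expect_equal(nrow(ref$exons), 0L)
  expect_equal(nrow(read_gene_bed(ref$bed_path)), 0L)
})

test_that("infeasible exon packing raises a named error", {
  cfg <- sim_config(seed = 1, genome_length = 5000L, n_genes = 40L)
  expect_error(simulate_reference(cfg), class = "crossvar_packing_error")
})

test_that("somatic tumor MAFs center on purity/2 (Monte Carlo, n = 1000)", {
  cfg <- sim_config(seed = 21, genome_length = 2000000L, n_genes = 0L,
                    purity = 0.3, maf_concentration = 400,
                    n_somatic_snvs = 1000L, n_germline_snvs = 0L)
  ref <- simulate_reference(cfg)
  sim <- simulate_callsets(cfg, ref)
  som <- sim$truth[sim$truth$status == "somatic", ]
  expect_equal(nrow(som), 1000L)
  expect_lt(abs(median(som$true_maf_tumor) - 0.15), 0.02)
})

test_that("full detection emits every truth variant into every call set", {
  cfg <- noise_free_config(seed = 4, genome_length = 200000L, n_genes = 5L,
                           n_somatic_snvs = 40L, n_germline_snvs = 60L)
  ref <- simulate_reference(cfg)
  sim <- simulate_callsets(cfg, ref)
  truth_keys <- paste(sim$truth$chrom, sim$truth$pos, sim$truth$ref,
                      sim$truth$alt)
  for (pf in c("WES", "WGS")) {
    for (cl in names(cfg$platform_sensitivity[[pf]])) {
      tumor_keys <- with(sim$calls[sim$calls$platform == pf &
                                     sim$calls$caller == cl &
                                     sim$calls$sample_role == "tumor", ],
                         paste(chrom, pos, ref, alt))
      expect_true(all(truth_keys %in% tumor_keys),
                  info = paste(pf, cl))
    }
  }
})

test_that("a single-class signature mixture yields only that class", {
  catalog <- disjoint_catalog()
  # sigA occupies the first 32 channels = the C>A and C>G classes; build a
  # pure C>T column instead so the class is unambiguous
  ct <- matrix(0, 96, 1, dimnames = list(context_channels(), "pureCT"))
  ct[grep("C>T", rownames(ct)), 1] <- 1 / 16
  cfg <- sim_config(seed = 13, genome_length = 200000L, n_genes = 0L,
                    n_somatic_snvs = 150L, n_germline_snvs = 0L,
                    catalog = ct, signature_mixture = c(pureCT = 1))
  ref <- simulate_reference(cfg)
  sim <- simulate_callsets(cfg, ref)
  som <- sim$truth[sim$truth$status == "somatic", ]
  cls <- ifelse(som$ref %in% c("C", "T"), paste0(som$ref, ">", som$alt),
                paste0(chartr("ACGT", "TGCA", som$ref), ">",
                       chartr("ACGT", "TGCA", som$alt)))
  expect_true(all(cls == "C>T"))
})

test_that("simulate_callsets and simulate_panel are seed-deterministic", {
  cfg <- small_config(seed = 99)
  ref <- simulate_reference(cfg)
  s1 <- simulate_callsets(cfg, ref)
  s2 <- simulate_callsets(cfg, ref)
  expect_identical(s1$calls, s2$calls)
  expect_identical(s1$truth, s2$truth)
  p1 <- simulate_panel(cfg, ref$exons)
  p2 <- simulate_panel(cfg, ref$exons)
  expect_identical(p1$counts, p2$counts)
  expect_identical(p1$multipliers, p2$multipliers)
})

test_that("a zero panel multiplier gives zero counts and ECS 0", {
  cfg <- small_config(seed = 2, panel_samples = 30L)
  ref <- simulate_reference(cfg)
  mult <- rep(1, 10); mult[3] <- 0
  cfg$gene_rate_multipliers <- mult
  pan <- simulate_panel(cfg, ref$exons)
  g3 <- unique(ref$exons$gene)[3]
  expect_equal(sum(pan$counts$count[pan$counts$gene == g3]), 0L)
  st <- build_panel_stats(pan$counts, ref$exons, n_samples = 30L)
  expect_equal(unname(ecs(st, g3)), 0)
})

test_that("equal multipliers drive every ECS toward 1 at panel size 1092", {
  cfg <- sim_config(seed = 8, genome_length = 300000L, n_genes = 12L,
                    panel_samples = 1092L, gene_rate_multipliers = rep(1, 12))
  ref <- simulate_reference(cfg)
  pan <- simulate_panel(cfg, ref$exons)
  st <- build_panel_stats(pan$counts, ref$exons, n_samples = 1092L)
  expect_true(all(abs(ecs(st) - 1) < 0.15))
})

test_that("simulated SV truth bookkeeping and contig coverage constraints", {
  cfg <- small_config(seed = 31)
  cfg$sv$n_germline_ins <- 3L; cfg$sv$n_somatic_ins <- 2L
  svs <- simulate_svs(cfg)
  ins <- svs$truth[svs$truth$sv_type == "insertion", ]
  expect_equal(nrow(ins), 5L)
  expect_equal(sum(ins$label == "germline"), 3L)
  # every germline contig is covered at >= 90% of positions
  for (id in ins$record[ins$label == "germline"]) {
    cov <- svs$coverage[svs$coverage$contig_id == id, ]
    expect_gte(mean(cov$depth >= 1), 0.90)
  }
  # determinism
  svs2 <- simulate_svs(cfg)
  expect_identical(svs$tumor, svs2$tumor)
  expect_identical(svs$coverage, svs2$coverage)
})
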