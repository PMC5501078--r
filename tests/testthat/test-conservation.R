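# The exonic gene conservation score.

two_gene_model <- function() {
  data.frame(gene = c("A", "A", "B"), chrom = "chr1",
             start = c(101L, 201L, 1001L), end = c(150L, 250L, 1300L),
             stringsAsFactors = FALSE)
}

test_that("the worked ECS example matches hand arithmetic", {
  # V_A = 4, L_tot = 400, L_A = 100, V_avg = 3, S = 2 -> 1600/600
  exons <- two_gene_model()
  counts <- data.frame(gene = c("A", "A", "B", "B"),
                       sample = c("s1", "s2", "s1", "s2"),
                       count = c(3L, 1L, 1L, 1L), stringsAsFactors = FALSE)
  st <- build_panel_stats(counts, exons)
  expect_equal(st$n_samples, 2L)
  expect_equal(unname(st$gene_length), c(100, 300))
  expect_equal(st$total_exonic_length, 400)
  expect_equal(st$avg_total_exonic_variants, 3)
  expect_equal(unname(ecs(st, "A")), 1600 / 600, tolerance = 1e-12)
  # gene at exactly the panel-average density scores 1
  # gene B: V_B = 2, L_B = 300 -> (2*400)/(300*3*2) = 800/1800
  expect_equal(unname(ecs(st, "B")), 800 / 1800, tolerance = 1e-12)
  # zero panel variants means maximally conserved
  counts0 <- counts; counts0$count[counts0$gene == "B"] <- 0L
  expect_equal(unname(ecs(build_panel_stats(counts0, exons), "B")), 0)
})

test_that("a gene at the panel-wide average per-bp density has ECS 1", {
  exons <- data.frame(gene = c("A", "B"), chrom = "chr1",
                      start = c(1L, 1001L), end = c(100L, 1300L),
                      stringsAsFactors = FALSE)
  # density 0.1 variants per bp per panel in both genes
  counts <- data.frame(gene = c("A", "B"), sample = "s1",
                       count = c(10L, 30L), stringsAsFactors = FALSE)
  st <- build_panel_stats(counts, exons)
  expect_equal(unname(ecs(st)), c(1, 1), tolerance = 1e-12)
})

test_that("the conservation threshold is strict at 0.01", {
  exons <- data.frame(gene = c("A", "B", "C"), chrom = "chr1",
                      start = c(1L, 2001L, 4001L),
                      end = c(1000L, 3000L, 5000L), stringsAsFactors = FALSE)
  # engineer ECS: V_g * 3000 / (1000 * V_avg * 1); choose V so that
  # ECS(A) = 0.009, ECS(B) = 0.01 exactly (scaled by 1000x counts)
  counts <- data.frame(gene = c("A", "B", "C"), sample = "s1",
                       count = c(9L, 10L, 2981L), stringsAsFactors = FALSE)
  st <- build_panel_stats(counts, exons)
  expect_equal(unname(ecs(st, "A")), 0.009, tolerance = 1e-12)
  expect_equal(unname(ecs(st, "B")), 0.010, tolerance = 1e-12)
  expect_equal(conserved_genes(st), "A")
})

test_that("length-weighted mean ECS is exactly 1 (conservation identity)", {
  cfg <- small_config(seed = 41, panel_samples = 25L)
  ref <- simulate_reference(cfg)
  pan <- simulate_panel(cfg, ref$exons)
  st <- build_panel_stats(pan$counts, ref$exons, n_samples = 25L)
  identity <- sum(ecs(st) * st$gene_length) / st$total_exonic_length
  expect_equal(identity, 1, tolerance = 1e-9)
})

test_that("ECS is invariant under duplicating the whole panel", {
  exons <- two_gene_model()
  counts <- data.frame(gene = c("A", "B"), sample = "s1", count = c(5L, 7L),
                       stringsAsFactors = FALSE)
  doubled <- rbind(counts,
                   transform(counts, sample = "s2"))
  e1 <- ecs(build_panel_stats(counts, exons))
  e2 <- ecs(build_panel_stats(doubled, exons))
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("TSV counts and a panel VCF describing the same data agree", {
  cfg <- small_config(seed = 43, panel_samples = 6L)
  ref <- simulate_reference(cfg)
  d <- file.path(tempdir(), "panelvcf")
  pan <- simulate_panel(cfg, ref$exons, dir = d, write_vcf = TRUE)
  # the VCF cannot represent zero-variant samples, so fix S explicitly
  st_tsv <- build_panel_stats(pan$counts_path, ref$exons, n_samples = 6L)
  st_vcf <- build_panel_stats(pan$vcf_path, ref$exons, n_samples = 6L)
  expect_equal(st_vcf$per_gene_variants, st_tsv$per_gene_variants)
  expect_equal(st_vcf$avg_total_exonic_variants,
               st_tsv$avg_total_exonic_variants)
  expect_equal(ecs(st_vcf), ecs(st_tsv), tolerance = 1e-12)
})

test_that("intronic panel variants are not counted", {
  exons <- two_gene_model()  # gene A has an intron at 151..200
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##INFO=<ID=PSAMPLE,Number=1,Type=String,Description="s">',
               '##INFO=<ID=FCLASS,Number=1,Type=String,Description="f">',
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t120\t.\tN\tA\t.\tPASS\tPSAMPLE=s1;FCLASS=nonsynonymous",
               "chr1\t170\t.\tN\tA\t.\tPASS\tPSAMPLE=s1;FCLASS=nonsynonymous",
               "chr1\t1100\t.\tN\tA\t.\tPASS\tPSAMPLE=s1;FCLASS=synonymous"),
             vcf)
  st <- build_panel_stats(vcf, exons)
  expect_equal(unname(st$per_gene_variants["A"]), 1)  # intronic one ignored
  expect_equal(unname(st$per_gene_variants["B"]), 0)  # synonymous ignored
  expect_equal(st$n_outside, 1L)
})

test_that("low-multiplier genes rank lowest by ECS", {
  cfg <- sim_config(seed = 47, genome_length = 2000000L, n_genes = 50L,
                    panel_samples = 200L)
  ref <- simulate_reference(cfg)
  pan <- simulate_panel(cfg, ref$exons)
  st <- build_panel_stats(pan$counts, ref$exons, n_samples = 200L)
  scores <- ecs(st)
  rho <- cor(pan$multipliers[names(scores)], scores, method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("degenerate panels raise named errors", {
  exons <- two_gene_model()
  empty <- data.frame(gene = character(0), sample = character(0),
                      count = integer(0), stringsAsFactors = FALSE)
  st <- build_panel_stats(empty, exons, n_samples = 5L)
  expect_error(ecs(st), class = "crossvar_ecs_degenerate")
  expect_error(build_panel_stats(empty, exons[0, ]), "empty")
})
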