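# Tiering, somatic extraction and candidate selection rules.

tier_of <- function(calls, support = NULL) {
  classify_tier(calls, support = support)$tier
}

test_that("cross-platform tier requires MAF > 5% on both platforms", {
  # called by DiBayes on WES (MAF 0.12), WGS pileup support at 0.07
  calls <- variant_calls("chr1", 100, "C", "T", "tumor", "WES", "dibayes",
                         100, 12)
  sup <- make_support_row("chr1", 100, "tumor", "WGS", 100, 7)
  expect_equal(tier_of(calls, sup), "cross_platform")

  # called on WGS at 0.30 with no WES record at all
  calls2 <- variant_calls("chr1", 200, "G", "A", "tumor", "WGS", "samtools",
                          100, 30)
  expect_equal(tier_of(calls2), "single_technology")

  # MAF exactly 0.05 on the other platform fails the strict bound
  sup3 <- make_support_row("chr1", 100, "tumor", "WGS", 100, 5)
  expect_equal(tier_of(calls, sup3), "single_technology")
  # ... and 0.051 passes
  sup4 <- make_support_row("chr1", 100, "tumor", "WGS", 1000, 51)
  expect_equal(tier_of(calls, sup4), "cross_platform")
})

test_that("zero-depth support is no support", {
  calls <- variant_calls("chr1", 100, "C", "T", "tumor", "WES", "gatk",
                         100, 12)
  sup <- make_support_row("chr1", 100, "tumor", "WGS", 0, 0)
  expect_equal(tier_of(calls, sup), "single_technology")
})

test_that("tiers partition the call union and roles are kept apart", {
  cfg <- small_config(seed = 17)
  ref <- simulate_reference(cfg)
  sim <- simulate_callsets(cfg, ref)
  cons <- classify_tier(sim$calls, support = sim$support)
  expect_true(all(cons$tier %in% c("cross_platform", "single_technology")))
  # one consolidated row per (role, key); together they cover the union
  keys <- unique(paste(sim$calls$sample_role, sim$calls$chrom, sim$calls$pos,
                       sim$calls$ref, sim$calls$alt))
  expect_equal(nrow(cons), length(keys))
})

test_that("somatic extraction applies normal-MAF and coverage rules", {
  tumor <- classify_tier(
    variant_calls("chr1", c(100, 200, 300), "C", "T", "tumor",
                  "WES", "gatk", 10, c(2, 2, 2)),
    support = rbind(make_support_row("chr1", 100, "tumor", "WGS", 10, 2),
                    make_support_row("chr1", 200, "tumor", "WGS", 10, 2),
                    make_support_row("chr1", 300, "tumor", "WGS", 10, 2)))
  normal <- tumor[0, ]
  sup <- rbind(
    make_support_row("chr1", 100, "normal", "WGS", 10, 0),  # clean normal
    make_support_row("chr1", 200, "normal", "WGS", 10, 4))  # germline 0.4
  out <- extract_somatic(tumor, normal, support = sup)
  expect_true(out$somatic[out$pos == 100])
  expect_false(out$somatic[out$pos == 200])
  expect_true(is.na(out$somatic[out$pos == 300]))  # no normal evidence

  # a variant called in the normal set is never somatic
  normal2 <- tumor[tumor$pos == 100, ]
  normal2$sample_role <- "normal"
  out2 <- extract_somatic(tumor, normal2, support = sup)
  expect_false(out2$somatic[out2$pos == 100])
})

test_that("tumor coverage below min_reads fails somatic reporting", {
  tumor <- classify_tier(
    variant_calls("chr1", 100, "C", "T", "tumor", "WES", "gatk", 2, 1),
    support = make_support_row("chr1", 100, "tumor", "WGS", 30, 9))
  sup <- make_support_row("chr1", 100, "normal", "WGS", 30, 0)
  out <- extract_somatic(tumor, tumor[0, ], support = sup, min_reads = 3L)
  expect_false(out$somatic)
  # same evidence but adequate depth passes
  tumor2 <- classify_tier(
    variant_calls("chr1", 100, "C", "T", "tumor", "WES", "gatk", 10, 5),
    support = make_support_row("chr1", 100, "tumor", "WGS", 30, 9))
  out2 <- extract_somatic(tumor2, tumor2[0, ], support = sup)
  expect_true(out2$somatic)
})

test_that("candidate selection implements the stopgain/damaging branches", {
  base <- data.frame(chrom = "chr1", pos = 1:5, ref = "C", alt = "T",
                     somatic = TRUE, novel = TRUE,
                     functional_class = c("stopgain", "nonsynonymous",
                                          "nonsynonymous", "nonsynonymous",
                                          "synonymous"),
                     damaging = c(FALSE, TRUE, TRUE, TRUE, TRUE),
                     conserved_position = c(FALSE, FALSE, TRUE, FALSE, TRUE),
                     gene = c("G1", "G2", "G3", "G4", "G5"),
                     stringsAsFactors = FALSE)
  out <- select_candidates(base, ecs_conserved = "G2")
  # stopgain (G1); damaging + conserved gene (G2); damaging + conserved
  # position (G3); G4 not conserved anywhere; G5 not protein-altering
  expect_setequal(out$gene, c("G1", "G2", "G3"))
  # non-novel or non-somatic variants are excluded
  base$novel <- FALSE
  expect_equal(nrow(select_candidates(base, "G2")), 0L)
})

test_that("filter report counts are monotone along the somatic chain", {
  cfg <- noise_free_config(seed = 23, genome_length = 300000L, n_genes = 10L,
                           n_somatic_snvs = 50L, n_germline_snvs = 80L,
                           panel_samples = 30L)
  ref <- simulate_reference(cfg)
  sim <- simulate_callsets(cfg, ref)
  cons <- classify_tier(sim$calls, support = sim$support)
  tumor <- extract_somatic(cons[cons$sample_role == "tumor", ],
                           cons[cons$sample_role == "normal", ],
                           support = sim$support)
  tumor <- annotate_variants(tumor, ref$exons, seed = 23)
  cand <- select_candidates(tumor)
  rep <- build_report(sim$calls, tumor, tumor, cand)
  g <- function(stage) rep$count[rep$stage == stage][1]
  expect_gte(g("cross_platform") + g("single_technology"), g("somatic"))
  expect_gte(g("somatic"), g("novel_somatic"))
  expect_gte(g("novel_somatic"), g("candidate"))
  # vacuous run
  rep0 <- build_report()
  expect_true(all(rep0$count == 0L))
})
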