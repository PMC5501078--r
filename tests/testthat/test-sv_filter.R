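# Structural-variant filtering: split reads, insertions, somatic matching.

mk_read <- function(n_hi = 100, n_lo = 0, parts = 1, mapped = 100) {
  list(base_qualities = c(rep(40L, n_hi), rep(20L, n_lo)),
       alignment_parts = replicate(parts, list(target = "chr1", start = 1,
                                               end = 50), simplify = FALSE),
       mapped_bases = mapped)
}

test_that("split-read filter applies all three criteria at their bounds", {
  pass <- mk_read(n_hi = 100, parts = 2, mapped = 95)
  expect_length(filter_split_reads(list(pass)), 1L)
  # 94 positions at quality >= 35 fail the >= 95 rule
  expect_length(filter_split_reads(list(mk_read(n_hi = 94, n_lo = 6))), 0L)
  # 95 exactly passes
  expect_length(filter_split_reads(list(mk_read(n_hi = 95, n_lo = 5))), 1L)
  # three alignment parts fail
  expect_length(filter_split_reads(list(mk_read(parts = 3))), 0L)
  # 91 mapped bases fail, 92 pass
  expect_length(filter_split_reads(list(mk_read(mapped = 91))), 0L)
  expect_length(filter_split_reads(list(mk_read(mapped = 92))), 1L)
})

test_that("insertion germline exclusion uses an inclusive 90% bound", {
  cov <- function(id, covered, len) {
    depth <- integer(len); depth[seq_len(covered)] <- 2L
    data.frame(contig_id = id, pos = seq_len(len), depth = depth,
               stringsAsFactors = FALSE)
  }
  res <- classify_insertions(rbind(cov("c90", 90, 100), cov("c89", 89, 100)))
  expect_equal(res$label[res$contig_id == "c90"], "germline")
  expect_equal(res$label[res$contig_id == "c89"], "somatic")
})

test_that("adding control coverage only moves labels somatic -> germline", {
  base <- data.frame(contig_id = "c", pos = 1:100,
                     depth = c(rep(1L, 85), rep(0L, 15)),
                     stringsAsFactors = FALSE)
  expect_equal(classify_insertions(base)$label, "somatic")
  more <- base; more$depth[86:95] <- 1L
  expect_equal(classify_insertions(more)$label, "germline")
})

test_that("planted insertion labels are recovered exactly", {
  cfg <- small_config(seed = 61)
  svs <- simulate_svs(cfg)
  res <- classify_insertions(svs$coverage)
  truth <- svs$truth[svs$truth$sv_type == "insertion", ]
  m <- merge(res, truth, by.x = "contig_id", by.y = "record")
  expect_equal(nrow(m), nrow(truth))
  expect_true(all(m$label.x == m$label.y))
})

test_that("somatic SV matching by type, overlap and breakpoint slop", {
  del <- function(id, s, e, role = "tumor") {
    data.frame(record = id, sv_type = "deletion", chrom1 = "chr1",
               start1 = s, end1 = e, chrom2 = NA, start2 = NA_integer_,
               end2 = NA_integer_, sample_role = role,
               stringsAsFactors = FALSE)
  }
  tra <- function(id, p1, p2, role = "tumor") {
    data.frame(record = id, sv_type = "translocation", chrom1 = "chr1",
               start1 = p1, end1 = p1, chrom2 = "chr2", start2 = p2,
               end2 = p2, sample_role = role, stringsAsFactors = FALSE)
  }
  tumor <- rbind(del("d1", 1000, 2000), del("d2", 5000, 6000),
                 tra("t1", 100, 200), tra("t2", 9000, 9100))
  control <- rbind(del("cd", 1000, 2000, "control"),
                   tra("ct", 150, 250, "control"))
  res <- somatic_svs(tumor, control)
  # identical deletion is germline; t1 breakpoints within 100 bp of control
  expect_setequal(res$somatic$record, c("d2", "t2"))
  # an inversion with no control inversion anywhere is somatic
  inv <- del("i1", 1000, 2000); inv$sv_type <- "inversion"
  expect_equal(somatic_svs(inv, control)$somatic$record, "i1")
})

test_that("non-overlapping counts merge mutually overlapping somatic SVs", {
  del <- function(id, s, e) {
    data.frame(record = id, sv_type = "deletion", chrom1 = "chr1",
               start1 = s, end1 = e, chrom2 = NA, start2 = NA_integer_,
               end2 = NA_integer_, sample_role = "tumor",
               stringsAsFactors = FALSE)
  }
  res <- somatic_svs(rbind(del("a", 100, 200), del("b", 150, 250)),
                     control = NULL)
  expect_equal(unname(res$somatic_counts["deletion"]), 2L)
  expect_equal(unname(res$non_overlapping["deletion"]), 1L)
})

test_that("planted SV labels are recovered, and degrade gracefully with jitter", {
  cfg <- small_config(seed = 67)
  svs <- simulate_svs(cfg)
  res <- somatic_svs(svs$tumor, svs$control)
  truth <- svs$truth[svs$truth$sv_type != "insertion", ]
  called_somatic <- truth$record %in% res$somatic$record
  expect_equal(called_somatic, truth$label == "somatic")
  # +/- 50 bp jitter on the control copies: recall stays >= 0.95
  recalls <- vapply(1:5, function(s) {
    cfg_j <- small_config(seed = 70 + s)
    svj <- simulate_svs(cfg_j, jitter_bp = 50L)
    rj <- somatic_svs(svj$tumor, svj$control)
    tj <- svj$truth[svj$truth$sv_type != "insertion", ]
    som <- tj$record[tj$label == "somatic"]
    mean(som %in% rj$somatic$record)
  }, numeric(1))
  expect_gte(mean(recalls), 0.95)
})

test_that("SV gene annotation distinguishes exonic/intronic/intergenic", {
  exons <- data.frame(gene = c("A", "A"), chrom = "chr1",
                      start = c(1000L, 3000L), end = c(1500L, 3500L),
                      stringsAsFactors = FALSE)
  svs <- data.frame(
    record = c("in_intron", "hits_exon", "far_away", "near"),
    sv_type = c("deletion", "deletion", "deletion", "insertion"),
    chrom1 = "chr1",
    start1 = c(1800L, 1400L, 500000L, 53500L),
    end1 = c(2500L, 1600L, 500100L, 53500L),
    chrom2 = NA, start2 = NA_integer_, end2 = NA_integer_,
    stringsAsFactors = FALSE)
  ann <- annotate_sv_genes(svs, exons)
  expect_equal(ann$region, c("intronic", "exonic", "intergenic",
                             "intergenic"))
  expect_equal(ann$genes[1:2], c("A", "A"))
  # 50 kb downstream of the gene end (3500): proximity flag set
  expect_true(ann$near_gene[ann$record == "near"])
  expect_equal(ann$gene_distance[ann$record == "near"], 53500L - 3500L - 1L)
  expect_false(ann$near_gene[ann$record == "far_away"])
})
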