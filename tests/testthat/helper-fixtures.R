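# Shared fixtures: tiny in-code VCFs, toy signature catalogs, small
# simulation configurations. Everything is generated at test time.

write_test_vcf <- function(records, path = tempfile(fileext = ".vcf"),
                           format = TRUE) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    if (format) c(
      '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
      '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">'),
    "##contig=<ID=chr1>",
    if (format)
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMPLE"
    else "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  writeLines(c(hdr, records), path)
  path
}

vcf_record <- function(pos, ref, alt, ref_reads, alt_reads,
                       chrom = "chr1", dp = ref_reads + alt_reads) {
  sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:AD:DP\t0/1:%d,%d:%d",
          chrom, pos, ref, alt, ref_reads, alt_reads, dp)
}

one_file_meta <- function(role = "tumor", platform = "WES",
                          caller = "gatk") {
  data.frame(sample_role = role, platform = platform, caller = caller,
             stringsAsFactors = FALSE)
}

# Three catalog profiles with pairwise disjoint support (32 channels each).
disjoint_catalog <- function() {
  m <- matrix(0, 96, 3, dimnames = list(context_channels(),
                                        c("sigA", "sigB", "sigC")))
  m[1:32, 1] <- 1 / 32
  m[33:64, 2] <- 1 / 32
  m[65:96, 3] <- 1 / 32
  m
}

# A small, fast configuration used where genome scale does not matter.
small_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(seed = seed, genome_length = 200000L, n_genes = 10L,
         n_somatic_snvs = 60L, n_germline_snvs = 100L,
         panel_samples = 40L),
    list(...))
  do.call(sim_config, args)
}

# Noise-free stated world: full detection, deterministic clonal MAFs,
# deterministic read support, no injected false positives.
noise_free_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(seed = seed, maf_concentration = Inf, read_noise = FALSE,
         fp_private = c(WES = 0L, WGS = 0L)),
    list(...))
  do.call(sim_config, args)
}

make_support_row <- function(chrom, pos, role, platform, depth, alt_reads,
                             ref = "C", alt = "T") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             sample_role = role, platform = platform, depth = depth,
             alt_reads = alt_reads, stringsAsFactors = FALSE)
}

# Brute-force kataegis oracle: enumerate all SNV index pairs (i, j), keep
# spans of <= window_bp containing >= min_snvs SNVs, merge overlapping
# spans. Independent of the two-pointer implementation.
brute_force_clusters <- function(snvs, rules) {
  out <- NULL
  for (rule in rules) {
    w <- rule[1]; k <- rule[2]
    for (ch in unique(snvs$chrom)) {
      pos <- sort(snvs$pos[snvs$chrom == ch])
      n <- length(pos)
      spans <- NULL
      for (i in seq_len(n)) {
        members <- pos[pos >= pos[i] & pos - pos[i] + 1 <= w]
        if (length(members) >= k) {
          spans <- rbind(spans, c(pos[i], max(members)))
        }
      }
      if (is.null(spans)) next
      spans <- spans[order(spans[, 1]), , drop = FALSE]
      merged <- list(spans[1, ])
      for (r in seq_len(nrow(spans))[-1]) {
        last <- merged[[length(merged)]]
        if (spans[r, 1] <= last[2]) {
          merged[[length(merged)]] <- c(last[1], max(last[2], spans[r, 2]))
        } else {
          merged[[length(merged) + 1]] <- spans[r, ]
        }
      }
      for (m in merged) {
        out <- rbind(out, data.frame(chrom = ch, start = m[1], end = m[2],
                                     n_snvs = sum(pos >= m[1] & pos <= m[2]),
                                     window_bp = w, min_snvs = k,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_snvs = integer(0),
                      window_bp = integer(0), min_snvs = integer(0),
                      stringsAsFactors = FALSE))
  }
  out[order(out$window_bp, out$chrom, out$start), , drop = FALSE]
}
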