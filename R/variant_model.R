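# Domain types and VCF readers/writers for variant-level data.
#
# A "call set" is represented as a data.frame with one row per VariantCall:
#   chrom, pos (1-based), ref, alt, sample_role (tumor|normal),
#   platform (WES|WGS), caller, depth, alt_reads, maf.
# A consolidated set adds: tier (cross_platform|single_technology), somatic,
# novel, and annotation columns (gene, functional_class, damaging,
# conserved_position, known_dbsnp, cancer_census).

SAMPLE_ROLES <- c("tumor", "normal")
PLATFORMS <- c("WES", "WGS")
FUNCTIONAL_CLASSES <- c("synonymous", "nonsynonymous", "stopgain",
                        "frameshift_indel", "nonframeshift_indel",
                        "intronic", "intergenic", "other")

#' Construct a validated table of variant calls
#'
#' @param chrom,pos,ref,alt Variant key fields; `pos` is 1-based.
#' @param sample_role `"tumor"` or `"normal"`.
#' @param platform `"WES"` or `"WGS"`.
#' @param caller Caller name (free string).
#' @param depth,alt_reads Read support; `0 <= alt_reads <= depth`.
#' @return A `data.frame` of calls with a computed `maf` column
#'   (`alt_reads / depth`, `NA` when `depth == 0`).
#' @export
variant_calls <- function(chrom, pos, ref, alt, sample_role, platform,
                          caller, depth, alt_reads) {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = toupper(as.character(ref)),
                   alt = toupper(as.character(alt)),
                   sample_role = as.character(sample_role),
                   platform = as.character(platform),
                   caller = as.character(caller),
                   depth = as.integer(depth),
                   alt_reads = as.integer(alt_reads),
                   stringsAsFactors = FALSE)
  validate_calls(df)
  df$maf <- ifelse(df$depth > 0, df$alt_reads / df$depth, NA_real_)
  df
}

validate_calls <- function(df) {
  assert_that(all(df$pos >= 1L), "variant positions must be >= 1")
  assert_that(all(df$ref != df$alt), "alt allele must differ from ref")
  assert_that(all(df$sample_role %in% SAMPLE_ROLES),
              "sample_role must be one of: %s",
              paste(SAMPLE_ROLES, collapse = ", "))
  assert_that(all(df$platform %in% PLATFORMS),
              "platform must be one of: %s", paste(PLATFORMS, collapse = ", "))
  assert_that(all(df$depth >= 0L) && all(df$alt_reads >= 0L) &&
                all(df$alt_reads <= df$depth),
              "read support must satisfy 0 <= alt_reads <= depth")
  invisible(df)
}

# Trim an allele pair to minimal representation and, when a reference is
# available, left-align indels so different caller representations merge.
normalize_allele <- function(pos, ref, alt, refseq = NULL, chrom = NULL) {
  # trim common suffix (keep >= 1 base each)
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  # trim common prefix, advancing pos
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  # left-align pure indels against the reference sequence
  if (!is.null(refseq) && !is.null(chrom) &&
      nchar(ref) != nchar(alt) && chrom %in% names(refseq)) {
    chromseq <- as.character(refseq[[chrom]])
    repeat {
      if (substr(ref, 1L, 1L) != substr(alt, 1L, 1L)) break
      long <- if (nchar(ref) > nchar(alt)) ref else alt
      if (pos <= 1L) break
      prev <- substr(chromseq, pos - 1L, pos - 1L)
      if (prev != substr(long, nchar(long), nchar(long))) break
      ref <- paste0(prev, substr(ref, 1L, nchar(ref) - 1L))
      alt <- paste0(prev, substr(alt, 1L, nchar(alt) - 1L))
      pos <- pos - 1L
    }
  }
  list(pos = pos, ref = ref, alt = alt)
}

# Cheap structural validation so parse failures carry a line number.
check_vcf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#"))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L || is.na(suppressWarnings(as.integer(f[2])))) {
      stop_named("crossvar_vcf_parse_error",
                 "malformed VCF record at line %d of %s", i, path)
    }
  }
  invisible(TRUE)
}

#' Read per-caller VCF call sets into a variant-call table
#'
#' Each input VCF carries calls for one sample on one platform from one
#' caller; the pairing is supplied via `metadata`. Multi-allelic records are
#' split into one call per ALT allele; indels are trimmed to minimal
#' representation and, when `reference` is given, left-aligned so that
#' callers reporting different representations merge on the same key.
#'
#' Depth and alt-read support are taken from the FORMAT fields `AD`/`DP`
#' of the first sample, falling back to the INFO fields `DP` and `AO`.
#'
#' @param paths Character vector of VCF paths.
#' @param metadata `data.frame` with one row per path and columns
#'   `sample_role`, `platform`, `caller`.
#' @param reference Optional `DNAStringSet` used to left-align indels.
#' @return A variant-call `data.frame` (see [variant_calls()]).
#' @export
read_callsets <- function(paths, metadata, reference = NULL) {
  assert_that(length(paths) == nrow(metadata),
              "one metadata row is required per VCF path")
  out <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    out[[i]] <- read_one_callset(paths[i], metadata$sample_role[i],
                                 metadata$platform[i], metadata$caller[i],
                                 reference)
  }
  do.call(rbind, out)
}

read_one_callset <- function(path, sample_role, platform, caller,
                             reference = NULL) {
  check_vcf_lines(path)
  vcf <- tryCatch(
    VariantAnnotation::readVcf(path),
    error = function(e) stop_named("crossvar_vcf_parse_error",
                                   "failed to parse %s: %s", path,
                                   conditionMessage(e)))
  if (length(vcf) == 0L) {
    return(variant_calls(character(0), integer(0), character(0),
                         character(0), character(0), character(0),
                         character(0), integer(0), integer(0)))
  }
  vcf <- VariantAnnotation::expand(vcf)
  n <- length(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(rr$REF)
  alt <- as.character(rr$ALT)

  geno <- VariantAnnotation::geno(vcf)
  depth <- NULL; alt_reads <- NULL
  if ("DP" %in% names(geno) && ncol(geno$DP) >= 1L) {
    depth <- as.integer(geno$DP[, 1L])
  }
  if ("AD" %in% names(geno) && ncol(geno$AD) >= 1L) {
    ad <- geno$AD
    if (length(dim(ad)) == 3L) {
      alt_reads <- as.integer(ad[, 1L, 2L])
      if (is.null(depth)) depth <- as.integer(ad[, 1L, 1L]) + alt_reads
    } else {
      adl <- ad[, 1L]
      alt_reads <- vapply(adl, function(x) as.integer(x[2L]), integer(1))
      if (is.null(depth)) {
        depth <- vapply(adl, function(x) as.integer(sum(x)), integer(1))
      }
    }
  }
  info <- VariantAnnotation::info(vcf)
  if (is.null(depth) && "DP" %in% colnames(info)) {
    depth <- as.integer(info$DP)
  }
  if (is.null(alt_reads) && "AO" %in% colnames(info)) {
    alt_reads <- as.integer(unlist(info$AO))
  }
  if (is.null(depth) || is.null(alt_reads) ||
      all(is.na(depth)) || all(is.na(alt_reads))) {
    stop_named("crossvar_missing_depth",
               "no depth/alt-read support (FORMAT AD/DP or INFO DP/AO) in %s",
               path)
  }
  norm <- Map(normalize_allele, as.list(pos), as.list(ref), as.list(alt),
              MoreArgs = list(refseq = reference), chrom = as.list(chrom))
  variant_calls(chrom = chrom,
                pos = vapply(norm, `[[`, integer(1), "pos"),
                ref = vapply(norm, `[[`, character(1), "ref"),
                alt = vapply(norm, `[[`, character(1), "alt"),
                sample_role = sample_role, platform = platform,
                caller = caller, depth = depth, alt_reads = alt_reads)
}

consolidated_info_header <- function() {
  c('##INFO=<ID=TIER,Number=1,Type=String,Description="Evidence tier">',
    '##INFO=<ID=SOMATIC,Number=0,Type=Flag,Description="Somatic variant">',
    '##INFO=<ID=NOVEL,Number=0,Type=Flag,Description="Not in dbSNP132">',
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=FCLASS,Number=1,Type=String,Description="Functional class">',
    '##INFO=<ID=DMG,Number=0,Type=Flag,Description="Predicted damaging">')
}

#' Write consolidated variants to VCF
#'
#' Serializes tier, somatic status, novelty and annotation into the INFO
#' keys `TIER`, `SOMATIC`, `NOVEL`, `GENE`, `FCLASS`, `DMG`. The output
#' round-trips through [read_consolidated()] without loss of these fields.
#'
#' @param variants Consolidated variant `data.frame` with at least the key
#'   columns `chrom, pos, ref, alt` and any of `tier, somatic, novel, gene,
#'   functional_class, damaging`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_consolidated <- function(variants, path) {
  hdr <- c("##fileformat=VCFv4.2", consolidated_info_header(),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  lines <- hdr
  if (nrow(variants) > 0L) {
    v <- variants[order(variants$chrom, variants$pos, variants$ref,
                        variants$alt), , drop = FALSE]
    info <- vapply(seq_len(nrow(v)), function(i) {
      parts <- sprintf("TIER=%s", if (is.null(v$tier)) "." else v$tier[i])
      if (!is.null(v$somatic) && isTRUE(v$somatic[i])) {
        parts <- c(parts, "SOMATIC")
      }
      if (!is.null(v$novel) && isTRUE(v$novel[i])) parts <- c(parts, "NOVEL")
      if (!is.null(v$gene) && !is.na(v$gene[i]) && nzchar(v$gene[i])) {
        parts <- c(parts, sprintf("GENE=%s", v$gene[i]))
      }
      if (!is.null(v$functional_class) && !is.na(v$functional_class[i])) {
        parts <- c(parts, sprintf("FCLASS=%s", v$functional_class[i]))
      }
      if (!is.null(v$damaging) && isTRUE(v$damaging[i])) {
        parts <- c(parts, "DMG")
      }
      paste(parts, collapse = ";")
    }, character(1))
    lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                              v$chrom, v$pos, v$ref, v$alt, info))
  }
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop_named(
                    "crossvar_io_error", "cannot write %s", path))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a consolidated VCF written by [write_consolidated()]
#'
#' @param path VCF path.
#' @return Consolidated variant `data.frame` with the serialized fields.
#' @export
read_consolidated <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  n <- length(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  gene <- if (n) as.character(info$GENE) else character(0)
  gene[is.na(gene)] <- ""
  fclass <- if (n) as.character(info$FCLASS) else character(0)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = as.character(unlist(rr$ALT)),
    tier = if (n) as.character(info$TIER) else character(0),
    somatic = if (n) as.logical(info$SOMATIC) else logical(0),
    novel = if (n) as.logical(info$NOVEL) else logical(0),
    gene = gene,
    functional_class = fclass,
    damaging = if (n) as.logical(info$DMG) else logical(0),
    stringsAsFactors = FALSE)
}
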