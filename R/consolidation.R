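# Cross-platform / cross-caller consolidation, MAF-threshold tiering,
# somatic extraction against the matched normal, and candidate selection.

variant_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

# Best MAF/depth evidence for one platform at one key, preferring call
# records and falling back to the pileup support table.
platform_evidence <- function(key_calls, support, platform, role,
                              chrom, pos, ref, alt) {
  pc <- key_calls[key_calls$platform == platform, , drop = FALSE]
  if (nrow(pc) > 0L) {
    best <- which.max(ifelse(is.na(pc$maf), -1, pc$maf))
    return(list(maf = pc$maf[best], depth = pc$depth[best]))
  }
  if (!is.null(support)) {
    s <- support[support$platform == platform &
                   support$sample_role == role &
                   support$chrom == chrom & support$pos == pos, ,
                 drop = FALSE]
    if ("ref" %in% names(s) && nrow(s) > 0L) {
      sm <- s[s$ref == ref & s$alt == alt, , drop = FALSE]
      if (nrow(sm) > 0L) s <- sm
    }
    if (nrow(s) > 0L) {
      maf <- ifelse(s$depth > 0L, s$alt_reads / s$depth, NA_real_)
      best <- which.max(ifelse(is.na(maf), -1, maf))
      return(list(maf = maf[best], depth = s$depth[best]))
    }
  }
  list(maf = NA_real_, depth = NA_integer_)
}

#' Classify variants into cross-platform and single-technology tiers
#'
#' A variant is *cross-platform* when it was called by at least one caller
#' on either platform and its mutant allele fraction is strictly greater
#' than `maf_threshold` on **both** platforms for the same sample role; the
#' non-calling platform's MAF may come from the pileup `support` table.
#' Everything else called is *single-technology*. MAF at a site with zero
#' or unknown depth counts as no support. Calls from different sample roles
#' at one key are classified separately.
#'
#' @param calls Variant-call data.frame (see [variant_calls()]).
#' @param support Optional pileup table with columns `chrom, pos,
#'   sample_role, platform, depth, alt_reads` (and optionally `ref, alt`).
#' @param maf_threshold Strict lower MAF bound on both platforms
#'   (default 0.05).
#' @return Consolidated data.frame: one row per (sample_role, key) with
#'   `tier`, per-platform `maf_WES`/`maf_WGS` and `depth_WES`/`depth_WGS`,
#'   `n_callers`, and `callers`.
#' @export
classify_tier <- function(calls, support = NULL, maf_threshold = 0.05) {
  if (nrow(calls) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      sample_role = character(0), tier = character(0),
                      maf_WES = numeric(0), maf_WGS = numeric(0),
                      depth_WES = integer(0), depth_WGS = integer(0),
                      n_callers = integer(0), callers = character(0),
                      stringsAsFactors = FALSE))
  }
  grp_key <- paste(calls$sample_role, variant_key(calls), sep = "|")
  idx <- split(seq_len(nrow(calls)), grp_key)
  rows <- lapply(idx, function(ii) {
    g <- calls[ii, , drop = FALSE]
    ev_wes <- platform_evidence(g, support, "WES", g$sample_role[1],
                                g$chrom[1], g$pos[1], g$ref[1], g$alt[1])
    ev_wgs <- platform_evidence(g, support, "WGS", g$sample_role[1],
                                g$chrom[1], g$pos[1], g$ref[1], g$alt[1])
    ok <- function(m) !is.na(m) && m > maf_threshold
    tier <- if (ok(ev_wes$maf) && ok(ev_wgs$maf)) "cross_platform"
            else "single_technology"
    data.frame(chrom = g$chrom[1], pos = g$pos[1], ref = g$ref[1],
               alt = g$alt[1], sample_role = g$sample_role[1], tier = tier,
               maf_WES = ev_wes$maf, maf_WGS = ev_wgs$maf,
               depth_WES = ev_wes$depth, depth_WGS = ev_wgs$depth,
               n_callers = length(unique(paste(g$platform, g$caller))),
               callers = paste(sort(unique(paste0(g$platform, ":", g$caller))),
                               collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$pos, out$ref, out$alt, out$sample_role), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag somatic variants against the matched normal
#'
#' A tumor variant is somatic when it is absent from every call set of the
#' matched normal **and** the normal MAF at that site (from the pileup
#' support table) does not exceed `normal_maf_max`, and the tumor site is
#' covered by at least `min_reads` reads on each platform where coverage is
#' known. Tumor variants with no normal evidence at all (no normal call and
#' no normal pileup record) are unclassifiable (`somatic = NA`), never
#' somatic.
#'
#' @param tumor Consolidated tumor variants (from [classify_tier()]).
#' @param normal Consolidated normal variants.
#' @param support Pileup support table (see [classify_tier()]).
#' @param normal_maf_max Maximum tolerated normal MAF (default 0.05).
#' @param min_reads Minimum read coverage per platform where known
#'   (default 3).
#' @return `tumor` with logical `somatic` column (TRUE/FALSE/NA).
#' @export
extract_somatic <- function(tumor, normal, support = NULL,
                            normal_maf_max = 0.05, min_reads = 3L) {
  if (nrow(tumor) == 0L) {
    tumor$somatic <- logical(0)
    return(tumor)
  }
  normal_keys <- if (nrow(normal)) variant_key(normal) else character(0)
  tkeys <- variant_key(tumor)
  nsup <- if (!is.null(support)) {
    support[support$sample_role == "normal", , drop = FALSE]
  }
  somatic <- logical(nrow(tumor))
  for (i in seq_len(nrow(tumor))) {
    # coverage requirement on each platform where depth is known
    depths <- c(tumor$depth_WES[i], tumor$depth_WGS[i])
    known <- !is.na(depths)
    if (any(known) && any(depths[known] < min_reads)) {
      somatic[i] <- FALSE
      next
    }
    if (tkeys[i] %in% normal_keys) {
      somatic[i] <- FALSE
      next
    }
    nmaf <- NA_real_
    if (!is.null(nsup)) {
      s <- nsup[nsup$chrom == tumor$chrom[i] & nsup$pos == tumor$pos[i], ,
                drop = FALSE]
      if (nrow(s) > 0L) {
        m <- ifelse(s$depth > 0L, s$alt_reads / s$depth, NA_real_)
        if (any(!is.na(m))) nmaf <- max(m, na.rm = TRUE)
      }
    }
    if (is.na(nmaf)) {
      somatic[i] <- NA   # unclassifiable: no matched-normal evidence
    } else {
      somatic[i] <- nmaf <= normal_maf_max
    }
  }
  tumor$somatic <- somatic
  tumor
}

#' Select candidate driver variants
#'
#' A somatic, novel, protein-altering variant is a candidate when it is a
#' stopgain, or predicted damaging and located either at a conserved
#' position or in a gene from the conserved set (ECS-based).
#'
#' @param somatic Consolidated variants with `somatic`, `novel` and
#'   annotation columns `functional_class`, `damaging`,
#'   `conserved_position`, `gene`.
#' @param ecs_conserved Character vector of conserved gene symbols.
#' @return The candidate subset of `somatic`.
#' @export
select_candidates <- function(somatic, ecs_conserved = character(0)) {
  if (nrow(somatic) == 0L) return(somatic)
  protein_altering <- somatic$functional_class %in% c("nonsynonymous",
                                                      "stopgain")
  stopgain <- somatic$functional_class == "stopgain"
  conserved <- (somatic$conserved_position %||% FALSE) |
    somatic$gene %in% ecs_conserved
  keep <- isTRUE_vec(somatic$somatic) & isTRUE_vec(somatic$novel) &
    protein_altering &
    (stopgain | (isTRUE_vec(somatic$damaging) & conserved))
  out <- somatic[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Per-stage filter report
#'
#' Counts the raw calls per caller, the per-platform union of keys, and the
#' consolidated tiers down to candidates, mirroring the pipeline's filter
#' chain.
#'
#' @param calls Raw variant-call data.frame.
#' @param consolidated Output of [classify_tier()] (tumor role).
#' @param somatic Output of [extract_somatic()].
#' @param candidates Output of [select_candidates()].
#' @param path Optional TSV output path.
#' @return data.frame `stage, group, count`, deterministically ordered.
#' @export
build_report <- function(calls = NULL, consolidated = NULL, somatic = NULL,
                         candidates = NULL, path = NULL) {
  rows <- list()
  add <- function(stage, group, count) {
    rows[[length(rows) + 1L]] <<- data.frame(stage = stage, group = group,
                                             count = as.integer(count),
                                             stringsAsFactors = FALSE)
  }
  if (!is.null(calls) && nrow(calls)) {
    cc <- table(paste(calls$platform, calls$caller, sep = ":"))
    for (nm in sort(names(cc))) add("raw_calls", nm, cc[[nm]])
    for (pf in sort(unique(calls$platform))) {
      add("platform_union", pf,
          length(unique(variant_key(calls[calls$platform == pf, ]))))
    }
  } else {
    add("raw_calls", "all", 0L)
  }
  if (!is.null(consolidated)) {
    add("cross_platform", "all", sum(consolidated$tier == "cross_platform"))
    add("single_technology", "all",
        sum(consolidated$tier == "single_technology"))
  } else {
    add("cross_platform", "all", 0L); add("single_technology", "all", 0L)
  }
  add("somatic", "all",
      if (is.null(somatic)) 0L else sum(isTRUE_vec(somatic$somatic)))
  add("novel_somatic", "all",
      if (is.null(somatic) || is.null(somatic$novel)) 0L
      else sum(isTRUE_vec(somatic$somatic) & isTRUE_vec(somatic$novel)))
  add("candidate", "all", if (is.null(candidates)) 0L else nrow(candidates))
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
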