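# Tumor cellularity estimation from the somatic MAF distribution.
#
# Model: clonal heterozygous somatic variants in a diploid tumor are
# carried by half of the tumor-derived reads, so the central somatic MAF
# equals purity / 2 and the cellularity estimate is twice the central MAF.

#' Estimate tumor cellularity from somatic mutant allele fractions
#'
#' Uses only MAFs inside `maf_window` (excluding sub-threshold noise and
#' homozygous/LOH tails). With `method = "mode"`, the central MAF is the
#' mode of a Gaussian kernel density estimate (bandwidth `bandwidth`)
#' restricted to the window; with `method = "median"`, the window median.
#' The estimate is twice the central MAF, clipped to (0, 1].
#'
#' @param somatic_mafs Numeric vector of somatic MAFs (fractions).
#' @param method `"mode"` (default) or `"median"`.
#' @param maf_window Half-open interval `(lo, hi]` of usable MAFs;
#'   default `(0.05, 0.5]`.
#' @param bandwidth Gaussian KDE bandwidth (default 0.03).
#' @param min_variants Minimum usable MAFs (default 20); fewer is an error,
#'   never a silent estimate.
#' @return Object of class `purity_estimate`: list with `estimate`,
#'   `n_variants`, `method`, `bandwidth`.
#' @export
estimate_purity <- function(somatic_mafs, method = c("mode", "median"),
                            maf_window = c(0.05, 0.5), bandwidth = 0.03,
                            min_variants = 20L) {
  method <- match.arg(method)
  x <- somatic_mafs[!is.na(somatic_mafs)]
  x <- x[x > maf_window[1] & x <= maf_window[2]]
  if (length(x) < min_variants) {
    stop_named("crossvar_insufficient_data",
               "only %d usable MAFs in (%g, %g]; need >= %d",
               length(x), maf_window[1], maf_window[2], min_variants)
  }
  central <- if (method == "median") {
    median(x)
  } else if (length(unique(x)) == 1L) {
    x[1]   # degenerate KDE: all mass at one point
  } else {
    d <- density(x, bw = bandwidth, from = maf_window[1], to = maf_window[2],
                 n = 2048)
    d$x[which.max(d$y)]
  }
  est <- min(max(2 * central, .Machine$double.eps), 1)
  structure(list(estimate = est, n_variants = length(x), method = method,
                 bandwidth = if (method == "mode") bandwidth else NA_real_),
            class = "purity_estimate")
}

#' @export
print.purity_estimate <- function(x, ...) {
  cat(sprintf("Tumor cellularity estimate: %.3f (%s of %d somatic MAFs)\n",
              x$estimate, x$method, x$n_variants))
  invisible(x)
}
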