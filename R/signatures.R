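# Mutational-signature analysis: de novo extraction by non-negative matrix
# factorization (multiplicative updates, Frobenius objective) and exposure
# refitting against a known catalog by non-negative least squares with
# small-exposure pruning.

#' Read / write a signature catalog TSV
#'
#' Rows are the 96 context channels in lexicographic pyrimidine order (first
#' column `context`), remaining columns one signature each; columns are
#' normalized to sum to 1 on read.
#'
#' @param path TSV path.
#' @param catalog 96 x k numeric matrix with channel rownames.
#' @return Matrix (read); `path` invisibly (write).
#' @export
read_catalog <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  assert_that("context" %in% names(df), "catalog TSV needs a context column")
  m <- as.matrix(df[, setdiff(names(df), "context"), drop = FALSE])
  rownames(m) <- df$context
  m <- m[context_channels(), , drop = FALSE]
  validate_catalog(sweep(m, 2, colSums(m), "/"))
}

#' @rdname read_catalog
#' @export
write_catalog <- function(catalog, path) {
  df <- data.frame(context = rownames(catalog), catalog,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_catalog <- function(catalog) {
  assert_that(nrow(catalog) == 96L, "catalog must have 96 context rows")
  assert_that(all(catalog >= 0), "catalog entries must be non-negative")
  assert_that(all(abs(colSums(catalog) - 1) < 1e-9),
              "catalog columns must sum to 1")
  catalog
}

# Lawson-Hanson active-set non-negative least squares: min ||Ax - b||, x >= 0.
nnls_fit <- function(A, b, tol = 1e-10) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- rep(FALSE, n)
  w <- crossprod(A, b - A %*% x)
  iter <- 0L
  while (any(!passive & w > tol) && iter < 30L * n) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      s <- numeric(n)
      Ap <- A[, passive, drop = FALSE]
      s[passive] <- qr.solve(crossprod(Ap), crossprod(Ap, b))
      if (all(s[passive] > tol)) break
      neg <- passive & s <= tol
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive <- passive & x > tol
      if (!any(passive)) { s <- numeric(n); break }
    }
    x <- s
    w <- crossprod(A, b - A %*% x)
  }
  as.numeric(x)
}

#' Refit signature exposures against a known catalog
#'
#' The normalized 96-channel count vector is decomposed over catalog
#' profiles by non-negative least squares. Exposures below `min_exposure`
#' are zeroed and the fit re-run on the surviving signatures until stable
#' (the pruning convention popularized by signature-refitting tools).
#' Exposures are reported as fractions of the spectrum; any unexplained
#' mass is `unknown_fraction`.
#'
#' @param counts96 Numeric length-96 count (or fraction) vector, channel
#'   order as [context_channels()].
#' @param catalog 96 x k catalog matrix, columns summing to 1.
#' @param min_exposure Pruning threshold on exposure fractions
#'   (default 0.06).
#' @return Object of class `exposure_fit`: `exposures` (named, length k),
#'   `unknown_fraction`, `reconstruction_error` (cosine distance between
#'   the input and the reconstructed spectrum).
#' @export
fit_exposures <- function(counts96, catalog, min_exposure = 0.06) {
  validate_catalog(catalog)
  assert_that(length(counts96) == 96L, "counts96 must have length 96")
  assert_that(all(counts96 >= 0), "counts must be non-negative")
  total <- sum(counts96)
  if (total <= 0) {
    stop_named("crossvar_empty_spectrum", "all-zero count vector")
  }
  b <- counts96 / total
  active <- rep(TRUE, ncol(catalog))
  repeat {
    x <- numeric(ncol(catalog))
    x[active] <- nnls_fit(catalog[, active, drop = FALSE], b)
    drop <- active & x < min_exposure & x > 0
    if (!any(drop)) break
    active <- active & !drop
    if (!any(active)) { x <- numeric(ncol(catalog)); break }
  }
  s <- sum(x)
  if (s > 1) x <- x / s
  recon <- as.numeric(catalog %*% x)
  cosdist <- if (sum(recon) == 0) 1 else
    1 - sum(b * recon) / sqrt(sum(b^2) * sum(recon^2))
  structure(list(exposures = setNames(x, colnames(catalog)),
                 unknown_fraction = max(0, 1 - sum(x)),
                 reconstruction_error = cosdist),
            class = "exposure_fit")
}

#' @export
print.exposure_fit <- function(x, ...) {
  nz <- x$exposures[x$exposures > 0]
  cat("Signature exposures:\n")
  for (nm in names(sort(nz, decreasing = TRUE))) {
    cat(sprintf("  %s: %.1f%%\n", nm, 100 * nz[[nm]]))
  }
  cat(sprintf("  unknown: %.1f%% (cosine distance %.4f)\n",
              100 * x$unknown_fraction, x$reconstruction_error))
  invisible(x)
}

# One multiplicative-update NMF run; returns W (96 x k), H (k x n), and the
# per-iteration Frobenius objective (non-increasing).
nmf_run <- function(V, k, max_iter = 500L, tol = 1e-8) {
  m <- nrow(V); n <- ncol(V)
  W <- matrix(runif(m * k, 0.1, 1), m, k)
  H <- matrix(runif(k * n, 0.1, 1), k, n)
  eps <- 1e-12
  obj <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V)) / (crossprod(W, W %*% H) + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    o <- sum((V - W %*% H)^2)
    obj <- c(obj, o)
    if (prev - o < tol * (1 + o)) break
    prev <- o
  }
  list(W = W, H = H, objective = obj)
}

#' De novo signature extraction by NMF
#'
#' Factorizes the 96 x n count matrix `V ~ W H` (multiplicative updates,
#' Frobenius objective) over `n_restarts` random restarts from the given
#' seed, keeping the best fit. Profiles (columns of `W`) are normalized to
#' sum to 1 and the per-sample contributions rescaled accordingly.
#'
#' @param counts96 96 x n matrix (samples in columns), or a length-96
#'   vector for a single pooled sample (then only `k = 1` is meaningful).
#' @param k Number of signatures to extract (default 2).
#' @param seed Integer seed for the restarts.
#' @param n_restarts Number of random restarts (default 50).
#' @param max_iter Update iterations per restart.
#' @return List with `profiles` (96 x k, columns sum to 1),
#'   `contributions` (k x n), `objective` (best final Frobenius error),
#'   `objective_trace` (per-iteration objective of the best run),
#'   `restart` (index of the winning restart).
#' @export
extract_signatures <- function(counts96, k = 2L, seed = 1L,
                               n_restarts = 50L, max_iter = 500L) {
  V <- if (is.matrix(counts96)) counts96 else matrix(counts96, ncol = 1L)
  assert_that(nrow(V) == 96L, "counts96 must have 96 rows")
  assert_that(all(V >= 0), "counts must be non-negative")
  if (k > ncol(V)) {
    stop_named("crossvar_rank_error",
               "k = %d exceeds the number of samples (%d)", k, ncol(V))
  }
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- nmf_run(V, k, max_iter = max_iter)
    o <- tail(fit$objective, 1L)
    if (is.null(best) || o < best$objective) {
      best <- list(W = fit$W, H = fit$H, objective = o,
                   objective_trace = fit$objective, restart = r)
    }
  }
  scale <- colSums(best$W)
  W <- sweep(best$W, 2, scale, "/")
  H <- best$H * scale
  rownames(W) <- if (is.matrix(counts96) && !is.null(rownames(counts96))) {
    rownames(counts96)
  } else context_channels()
  colnames(W) <- sprintf("signature_%d", seq_len(k))
  rownames(H) <- colnames(W)
  list(profiles = W, contributions = H, objective = best$objective,
       objective_trace = best$objective_trace, restart = best$restart)
}

#' Cosine similarity between two non-negative vectors
#'
#' @param a,b Numeric vectors of equal length.
#' @return Cosine similarity in `[0, 1]` for non-negative input.
#' @export
cosine_similarity <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}
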