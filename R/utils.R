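# Shared numerical helpers: pseudo-inverse, kurtosis, matching, RNG substreams.

#' Moore-Penrose pseudo-inverse
#'
#' SVD-based pseudo-inverse. Singular values below
#' `max(dim(x)) * .Machine$double.eps * sigma_max` are treated as zero,
#' the usual rank cutoff.
#'
#' @param x numeric matrix.
#' @param tol optional absolute singular-value cutoff; default as above.
#' @return the pseudo-inverse, `ncol(x) x nrow(x)`.
#' @export
pinv <- function(x, tol = NULL) {
  x <- as.matrix(x)
  s <- svd(x)
  if (is.null(tol)) tol <- max(dim(x)) * .Machine$double.eps * max(s$d, 0)
  keep <- s$d > tol
  if (!any(keep)) return(matrix(0, ncol(x), nrow(x)))
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Sample excess kurtosis
#'
#' Fourth standardized moment minus 3 (population value 0 for a Gaussian,
#' 3 for a Laplace distribution).
#'
#' @param x numeric vector.
#' @return excess kurtosis (scalar).
#' @export
excess_kurtosis <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) return(NA_real_)
  mean((x - m)^4) / s2^2 - 3
}

#' Fisher r-to-z transform with saturation guard
#'
#' `atanh(r)` after capping `|r|` at `1 - cap` so the result stays finite
#' for degenerate (perfectly correlated) inputs.
#'
#' @param r correlations in `[-1, 1]`.
#' @param cap saturation margin, default `1e-6`.
#' @return Fisher z values.
#' @export
fisher_z <- function(r, cap = 1e-6) {
  r <- pmin(pmax(r, -1 + cap), 1 - cap)
  atanh(r)
}

# Deterministic per-unit RNG substream: a small integer hash of (seed, index)
# kept below 2^31 so set.seed() accepts it. Gives per-subject reproducibility
# independent of iteration order.
substream_seed <- function(seed, index) {
  h <- (as.double(seed) %% 2147483647) + 1
  for (k in c(index + 1, 97)) {
    h <- (h * 48271 + k) %% 2147483647
  }
  as.integer(h)
}

with_substream <- function(seed, index, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, index))
  force(expr)
}

#' Match rows of two source matrices by absolute correlation
#'
#' Greedy matching without replacement: repeatedly picks the remaining
#' (row of `a`, row of `b`) pair with the largest `|r|` over the feature
#' columns. Used for comparing recovered components against planted or
#' full-sample components, where component order and sign are arbitrary.
#'
#' @param a,b matrices with components in rows and a shared feature space
#'   in columns. `a` may have fewer rows than `b`.
#' @return data.frame with columns `row_a`, `row_b`, `abs_r`.
#' @export
match_sources <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(ncol(a) == ncol(b), nrow(a) <= nrow(b))
  cc <- abs(cor(t(a), t(b)))
  n <- nrow(a)
  out <- data.frame(row_a = integer(n), row_b = integer(n), abs_r = numeric(n))
  for (k in seq_len(n)) {
    idx <- arrayInd(which.max(cc), dim(cc))
    out$row_a[k] <- idx[1]; out$row_b[k] <- idx[2]
    out$abs_r[k] <- cc[idx[1], idx[2]]
    cc[idx[1], ] <- -Inf
    cc[, idx[2]] <- -Inf
  }
  out[order(out$row_a), ]
}

# Repair a correlation matrix to positive definiteness: clip eigenvalues at
# `floor`, reconstruct, re-normalize to unit diagonal.
nearest_pd_corr <- function(R, floor = 1e-6) {
  R <- (R + t(R)) / 2
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= floor) return(R)
  vals <- pmax(e$values, floor)
  R2 <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(R2))
  R2 <- R2 / tcrossprod(d)
  diag(R2) <- 1
  R2
}

# Internal column z-score that errors informatively on zero variance.
zscore_cols <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  if (any(sdv == 0)) stop("zero-variance column(s): ",
                          paste(head(which(sdv == 0), 5), collapse = ", "))
  sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
}
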