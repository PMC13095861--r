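# Time-course post-processing and tapered sliding-window FNC estimation.

#' Post-process ICN time courses
#'
#' Standard dFNC preprocessing chain: per-column linear detrend, despiking
#' by clipping samples beyond median +/- 4 MAD to the boundary, optional
#' regression of motion parameters (and their temporal derivatives, if the
#' caller includes them), zero-phase band-pass filtering (5th-order
#' Butterworth applied forward and backward), and re-standardization of
#' every column to unit variance.
#'
#' @param tc numeric matrix, time x ICNs.
#' @param tr_seconds repetition time in seconds.
#' @param motion optional matrix of nuisance regressors (time x q), e.g.
#'   realignment parameters plus derivatives; skipped when `NULL`.
#' @param band band-pass edges in Hz, `c(low, high)`; both must lie below
#'   the Nyquist frequency `1 / (2 tr_seconds)`.
#' @param despike_mad clipping threshold in MAD units (default 4).
#' @return processed matrix, same dimensions as `tc`.
#' @export
postprocess_timecourses <- function(tc, tr_seconds, motion = NULL,
                                    band = c(0.01, 0.15), despike_mad = 4) {
  tc <- as.matrix(tc)
  nt <- nrow(tc)
  nyq <- 1 / (2 * tr_seconds)
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < nyq))
    stop("band must satisfy 0 < low < high < Nyquist (", signif(nyq, 4), " Hz)")

  # Linear detrend.
  t_idx <- seq_len(nt)
  X <- cbind(1, t_idx)
  tc <- tc - X %*% qr.coef(qr(X), tc)

  # Despike: clip to median +/- k*MAD per column.
  for (j in seq_len(ncol(tc))) {
    m <- median(tc[, j]); s <- mad(tc[, j])
    if (s > 0) tc[, j] <- pmin(pmax(tc[, j], m - despike_mad * s),
                               m + despike_mad * s)
  }

  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    stopifnot(nrow(motion) == nt)
    Xm <- cbind(1, motion)
    tc <- tc - Xm %*% qr.coef(qr(Xm), tc)
  }

  bf <- signal::butter(5, band / nyq, type = "pass")
  for (j in seq_len(ncol(tc)))
    tc[, j] <- signal::filtfilt(bf, tc[, j])

  sdv <- apply(tc, 2, sd)
  if (any(sdv < .Machine$double.eps * nt))
    stop("constant column after filtering: ICN ",
         paste(which(sdv < .Machine$double.eps * nt), collapse = ", "))
  sweep(tc, 2, sdv, "/")
}

#' Tapered sliding-window weights
#'
#' Convolves a rectangular window of `window_trs` ones with a Gaussian
#' kernel of standard deviation `sigma_trs` (support +/- 3 sigma), then
#' normalizes to sum 1. The result is symmetric, strictly positive, with
#' support `window_trs + 2 * ceiling(3 * sigma_trs)`.
#'
#' @param window_trs rectangle length in TRs (>= 4); default 20.
#' @param sigma_trs Gaussian sigma in TRs; default 3.
#' @return numeric weight vector summing to 1.
#' @export
make_taper <- function(window_trs = 20, sigma_trs = 3) {
  stopifnot(window_trs >= 4, sigma_trs >= 0)
  rect <- rep(1, window_trs)
  if (sigma_trs == 0) return(rect / sum(rect))
  half <- ceiling(3 * sigma_trs)
  kern <- exp(-0.5 * ((-half):half / sigma_trs)^2)
  w <- stats::convolve(rect, rev(kern), type = "open")
  w <- (w + rev(w)) / 2 # enforce exact symmetry against FFT round-off
  w / sum(w)
}

#' Graphical-lasso covariance estimate
#'
#' L1-penalized sparse inverse-covariance estimation (block coordinate
#' descent with a lasso inner solver; the diagonal is unpenalized),
#' returning both the precision matrix and its inverse.
#'
#' @param S sample covariance matrix.
#' @param lambda L1 penalty (>= 0); 0 returns `S` untouched.
#' @param max_iter,tol outer-loop controls.
#' @return list with `w` (covariance estimate), `theta` (precision),
#'   `converged`, `iterations`.
#' @export
graphical_lasso <- function(S, lambda, max_iter = 100, tol = 1e-4) {
  S <- as.matrix(S)
  stopifnot(nrow(S) == ncol(S), lambda >= 0)
  if (lambda == 0)
    return(list(w = S, theta = solve(S + diag(1e-12, nrow(S))),
                converged = TRUE, iterations = 0L))
  res <- glasso_cpp(S, lambda, as.integer(max_iter), tol)
  if (!res$converged)
    warning("graphical lasso did not converge in ", max_iter, " iterations")
  res
}

#' Tapered sliding-window FNC series
#'
#' For each window position (stride 1 TR by default, windows half-open
#' `[t, t + support)` on 1-based start indices) the demeaned samples are
#' weighted by the taper, a weighted covariance is formed, the covariance
#' is re-estimated from an L1-regularized precision matrix (graphical
#' lasso, diagonal unpenalized), converted to correlation, and the upper
#' triangle is Fisher r-to-z transformed into the pair vector.
#'
#' @param tc time x ICNs matrix (post-processed).
#' @param taper weight vector from [make_taper()].
#' @param stride window step in TRs (default 1).
#' @param glasso_lambda graphical-lasso penalty; `0` skips regularization
#'   and uses the tapered sample correlation directly.
#' @param subject optional subject id carried through.
#' @return object of class `wfnc`: list with `z` (n_windows x n_pairs
#'   Fisher-z matrix), `starts` (1-based window start indices), `n_icns`,
#'   `subject`, and `failed` (indices of dropped windows, if any).
#' @export
windowed_fnc <- function(tc, taper = make_taper(), stride = 1,
                         glasso_lambda = 0.1, subject = NA_character_) {
  tc <- as.matrix(tc)
  nt <- nrow(tc); p <- ncol(tc)
  support <- length(taper)
  if (nt < support) stop("time series shorter than taper support (", support, ")")
  starts <- seq(1, nt - support + 1, by = stride)
  npair <- n_fnc_pairs(p)
  Z <- matrix(NA_real_, length(starts), npair)
  failed <- integer(0)
  ut <- upper.tri(matrix(0, p, p))
  idx <- pair_index(p)
  for (w in seq_along(starts)) {
    rows <- starts[w]:(starts[w] + support - 1)
    xw <- tc[rows, , drop = FALSE]
    mu <- colSums(xw * taper)
    xc <- sweep(xw, 2, mu, "-") * sqrt(taper)
    S <- crossprod(xc) / (1 - sum(taper^2)) # unbiased weighted covariance
    if (glasso_lambda > 0) {
      # Penalty applied on the correlation scale, as is conventional.
      dsd <- sqrt(diag(S))
      R <- S / tcrossprod(dsd)
      fit <- tryCatch(glasso_cpp(R, glasso_lambda, 100L, 1e-4),
                      error = function(e) NULL)
      if (is.null(fit) || !fit$converged) {
        failed <- c(failed, w)
        next
      }
      C <- fit$w
      R <- C / tcrossprod(sqrt(diag(C)))
    } else {
      R <- S / tcrossprod(sqrt(diag(S)))
    }
    Z[w, ] <- fisher_z(R[cbind(idx$i, idx$j)])
  }
  if (length(failed)) {
    if (length(failed) >= 0.01 * length(starts))
      warning(sprintf("%d/%d windows dropped (graphical lasso failures)%s",
                      length(failed), length(starts),
                      if (!is.na(subject)) paste0(" for subject ", subject) else ""))
    keep <- setdiff(seq_along(starts), failed)
    Z <- Z[keep, , drop = FALSE]
    starts <- starts[keep]
  }
  structure(list(z = Z, starts = starts, n_icns = p, subject = subject,
                 failed = failed), class = "wfnc")
}

#' @export
print.wfnc <- function(x, ...) {
  cat(sprintf("Windowed FNC series%s: %d windows x %d pairs (%d ICNs)\n",
              if (!is.na(x$subject)) paste0(" [", x$subject, "]") else "",
              nrow(x$z), ncol(x$z), x$n_icns))
  invisible(x)
}
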