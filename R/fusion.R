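# Joint ICA fusion of the SNP block with one state's sa-dFNC block:
# modality balancing, scree-knee model-order selection, PCA reduction,
# Infomax unmixing, super-Gaussian flagging, and split-half stability.

#' Balance and concatenate the two modality blocks
#'
#' Restricts both blocks to their shared subjects (kept in the SNP block's
#' order), z-scores every feature across subjects (zero-variance features
#' are dropped with a warning), rescales each modality block by
#' `1/sqrt(block feature count)` so both contribute equal expected total
#' variance, and concatenates horizontally.
#'
#' @param x_snp subjects x p1 matrix (row names = subject ids).
#' @param x_dfnc subjects x p2 matrix (row names = subject ids).
#' @param balance if `FALSE`, skip the block rescaling (sensitivity
#'   analysis); features are still z-scored.
#' @param state optional state index carried through.
#' @return object of class `fusion_input`: `X` (subjects x (p1+p2)),
#'   `p_snp`, `p_dfnc`, `subject_ids`, `snp_ids`, `pair_ids`, `dropped`.
#' @export
balance_and_concatenate <- function(x_snp, x_dfnc, balance = TRUE, state = NA_integer_) {
  x_snp <- as.matrix(x_snp); x_dfnc <- as.matrix(x_dfnc)
  if (!is.null(rownames(x_snp)) && !is.null(rownames(x_dfnc))) {
    shared <- intersect(rownames(x_snp), rownames(x_dfnc))
    if (!length(shared)) stop("no shared subjects between blocks")
    x_snp <- x_snp[shared, , drop = FALSE]
    x_dfnc <- x_dfnc[shared, , drop = FALSE]
  } else if (nrow(x_snp) != nrow(x_dfnc)) {
    stop("blocks have different subject counts and no row names to match on")
  }
  prep <- function(x, tag) {
    sdv <- apply(x, 2, sd)
    dropped <- colnames(x)[sdv == 0]
    if (is.null(dropped)) dropped <- which(sdv == 0)
    if (any(sdv == 0)) {
      warning(sum(sdv == 0), " zero-variance ", tag, " feature(s) dropped")
      x <- x[, sdv > 0, drop = FALSE]
    }
    list(z = zscore_cols(x), dropped = dropped)
  }
  ps <- prep(x_snp, "SNP"); pd <- prep(x_dfnc, "dFNC")
  zs <- ps$z; zd <- pd$z
  if (is.null(colnames(zs)) && ncol(zs))
    colnames(zs) <- paste0("snp", seq_len(ncol(zs)))
  if (is.null(colnames(zd)) && ncol(zd))
    colnames(zd) <- paste0("pair", seq_len(ncol(zd)))
  if (balance) {
    zs <- zs / sqrt(ncol(zs))
    zd <- zd / sqrt(ncol(zd))
  }
  structure(list(X = cbind(zs, zd), p_snp = ncol(zs), p_dfnc = ncol(zd),
                 subject_ids = rownames(zs), snp_ids = colnames(zs),
                 pair_ids = colnames(zd),
                 dropped = c(ps$dropped, pd$dropped), state = state,
                 balanced = balance),
            class = "fusion_input")
}

#' Knee of an eigenvalue scree by maximum distance to the chord
#'
#' Scales the scree to the unit square, draws the chord from the first to
#' the last point, and returns the index of the point farthest from it.
#'
#' @param eigenvalues decreasing eigenvalue sequence.
#' @return knee index (a model-order estimate).
#' @export
scree_knee <- function(eigenvalues) {
  m <- length(eigenvalues)
  stopifnot(m >= 3)
  x <- (seq_len(m) - 1) / (m - 1)
  y <- (eigenvalues - eigenvalues[m]) / (eigenvalues[1] - eigenvalues[m])
  # distance from (x, y) to the chord joining (0, y1) and (1, ym)
  d <- abs((y[m] - y[1]) * x - (1 - 0) * y + y[1]) / sqrt((y[m] - y[1])^2 + 1)
  which.max(d)
}

#' Combine per-matrix knee estimates into one model order
#'
#' The shared model order is the median of the individual knee estimates,
#' optionally raised to the smallest order whose retained variance meets
#' `floor_variance` on every matrix in `floor_screes`.
#'
#' @param knees integer vector of knee estimates.
#' @param floor_variance minimum retained variance fraction (0 disables).
#' @param floor_screes optional list of eigenvalue vectors the floor must
#'   hold on (typically the dFNC matrices only).
#' @return integer model order.
#' @export
model_order_from_knees <- function(knees, floor_variance = 0, floor_screes = NULL) {
  C <- as.integer(round(median(knees)))
  if (floor_variance > 0 && length(floor_screes)) {
    need <- vapply(floor_screes, function(ev) {
      frac <- cumsum(ev) / sum(ev)
      idx <- which(frac >= floor_variance)
      if (!length(idx)) stop("variance floor ", floor_variance,
                             " unreachable within ", length(ev), " components")
      idx[1]
    }, 0L)
    C <- max(C, need)
  }
  C
}

#' Eigenvalue scree of a subject-covariance
#'
#' @param x subjects x features matrix.
#' @return decreasing eigenvalues of the feature-space covariance summary
#'   (squared singular values of the column-centered matrix / (n - 1)).
#' @export
covariance_scree <- function(x) {
  x <- as.matrix(x)
  xc <- sweep(x, 2, colMeans(x), "-")
  svd(xc, nu = 0, nv = 0)$d^2 / (nrow(x) - 1)
}

#' Select the shared jICA model order from several matrices
#'
#' Computes the eigenvalue scree of each input matrix, estimates its knee
#' by [scree_knee()], and combines the knees by their median, raised if
#' necessary so the retained variance reaches `floor_variance` on every
#' matrix listed in `floor_on`.
#'
#' @param eigen_inputs list of subjects x features matrices (e.g. the four
#'   sa-dFNC matrices plus the SNP matrix).
#' @param floor_variance minimum retained variance fraction; default 0.
#' @param floor_on indices of `eigen_inputs` the floor applies to
#'   (default: all).
#' @return integer model order with attribute `knees`.
#' @export
select_model_order <- function(eigen_inputs, floor_variance = 0,
                               floor_on = seq_along(eigen_inputs)) {
  stopifnot(length(eigen_inputs) >= 1)
  screes <- lapply(eigen_inputs, covariance_scree)
  knees <- vapply(screes, scree_knee, 0L)
  C <- model_order_from_knees(knees, floor_variance, screes[floor_on])
  if (C >= min(vapply(eigen_inputs, nrow, 0L)))
    stop("selected model order ", C, " is not below the subject count")
  structure(C, knees = knees)
}

# Row skewness used for the component sign convention.
row_skewness <- function(S) {
  m <- rowMeans(S)
  s <- sqrt(rowMeans((S - m)^2))
  rowMeans((S - m)^3) / s^3
}

#' Infomax joint ICA
#'
#' Reduces the concatenated data to `C` whitened rows over features by
#' SVD-based PCA, then runs Infomax ICA (logistic nonlinearity, natural
#' gradient, block updates with learning-rate annealing when the angle
#' between successive weight updates exceeds 60 degrees). Sources are
#' standardized to unit variance with the scaling absorbed into the
#' loadings, signed so every source row has positive skewness, and ordered
#' by descending explained data variance.
#'
#' @param x a [balance_and_concatenate()] result, or a plain subjects x
#'   features matrix (optionally with `p_snp`/`p_dfnc` given).
#' @param C model order (< subjects).
#' @param seed integer seed for the sample-order permutations.
#' @param max_iter,tol Infomax stopping controls.
#' @param p_snp,p_dfnc column partition when `x` is a plain matrix.
#' @return object of class `fusion_result`: `A` (subjects x C), `S`
#'   (C x features), `C`, `p_snp`, `p_dfnc`, `kurtosis` (excess, per joint
#'   source row), `super_gaussian` flags, `converged`, `iterations`,
#'   `pca` (basis for rank-C reconstruction), ids, `state`.
#' @export
infomax_jica <- function(x, C, seed = 1, max_iter = 512, tol = 1e-6,
                         p_snp = NULL, p_dfnc = NULL) {
  if (inherits(x, "fusion_input")) {
    X <- x$X; p_snp <- x$p_snp; p_dfnc <- x$p_dfnc
    subject_ids <- x$subject_ids; state <- x$state
    feature_ids <- c(x$snp_ids, x$pair_ids)
  } else {
    X <- as.matrix(x)
    subject_ids <- rownames(X); state <- NA_integer_
    feature_ids <- colnames(X)
    if (is.null(p_snp)) { p_snp <- ncol(X); p_dfnc <- 0L }
  }
  C <- as.integer(C)
  n <- nrow(X); p <- ncol(X)
  if (n <= C) stop("model order C must be below the subject count")

  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu, "-")
  sv <- svd(Xc)
  rank <- sum(sv$d > max(dim(Xc)) * .Machine$double.eps * sv$d[1])
  if (rank < C) stop("data rank ", rank, " is below model order C = ", C,
                     "; lower C")
  V <- sv$v[, seq_len(C), drop = FALSE]
  d <- sv$d[seq_len(C)]
  Z <- sqrt(p) * t(V) # C x p, rows uncorrelated with unit variance

  # Infomax with logistic nonlinearity and natural-gradient block updates.
  W <- diag(C)
  lrate <- 0.00065 / log(max(C, 2))
  block <- max(8L, min(p, ceiling(5 * log(p))))
  old_dW <- NULL
  change <- Inf
  iter <- 0L
  set.seed(substream_seed(seed, 4096L))
  while (iter < max_iter) {
    iter <- iter + 1L
    W_old <- W
    perm <- sample.int(p)
    for (b0 in seq(1, p - block + 1, by = block)) {
      idx <- perm[b0:(b0 + block - 1)]
      u <- W %*% Z[, idx, drop = FALSE]
      y <- 1 / (1 + exp(-u))
      W <- W + lrate * (diag(block, C) + (1 - 2 * y) %*% t(u)) %*% W
      if (!all(is.finite(W)) || max(abs(W)) > 1e8) {
        # blow-up: restart colder
        W <- diag(C); old_dW <- NULL
        lrate <- lrate * 0.5
        break
      }
    }
    dW <- W - W_old
    change <- sum(dW^2)
    if (!is.null(old_dW)) {
      denom <- sqrt(sum(dW^2) * sum(old_dW^2))
      if (denom > 0 && sum(dW * old_dW) / denom < cos(60 * pi / 180))
        lrate <- lrate * 0.9
    }
    old_dW <- dW
    if (change < tol) break
  }
  converged <- change < tol
  if (!converged)
    warning("Infomax did not converge within ", max_iter,
            " iterations (last weight change ", signif(change, 3), ")")

  S <- W %*% Z # C x p
  # unit-variance source rows, positive skewness, order by explained variance
  sdr <- sqrt(rowMeans(S^2) - rowMeans(S)^2)
  S <- S / sdr
  sgn <- ifelse(row_skewness(S) < 0, -1, 1)
  S <- S * sgn
  A <- Xc %*% pinv(S)
  ord <- order(colSums(A^2), decreasing = TRUE)
  S <- S[ord, , drop = FALSE]
  A <- A[, ord, drop = FALSE]
  rownames(S) <- colnames(A) <- paste0("C", seq_len(C))
  if (!is.null(subject_ids)) rownames(A) <- subject_ids
  if (!is.null(feature_ids)) colnames(S) <- feature_ids

  kurt <- apply(S, 1, excess_kurtosis)
  res <- structure(list(
    A = A, S = S, C = C, p_snp = p_snp, p_dfnc = p_dfnc,
    kurtosis = kurt, super_gaussian = kurt > 0,
    converged = converged, iterations = iter,
    pca = list(v = V, d = d, center = mu),
    subject_ids = subject_ids, feature_ids = feature_ids,
    state = state, seed = seed), class = "fusion_result")
  res
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf("jICA fusion result%s: %d subjects x %d components, %d SNP + %d dFNC features\n",
              if (!is.na(x$state)) paste0(" (state ", x$state, ")") else "",
              nrow(x$A), x$C, x$p_snp, x$p_dfnc))
  cat(sprintf("  converged: %s (%d iterations); %d/%d super-Gaussian components\n",
              x$converged, x$iterations, sum(x$super_gaussian), x$C))
  invisible(x)
}

#' SNP / dFNC sub-blocks of a source matrix
#'
#' @param result a `fusion_result`.
#' @param modality `"snp"` or `"dfnc"`.
#' @return the C x p_modality sub-matrix of `S`.
#' @export
source_block <- function(result, modality = c("snp", "dfnc")) {
  modality <- match.arg(modality)
  if (modality == "snp") result$S[, seq_len(result$p_snp), drop = FALSE]
  else result$S[, result$p_snp + seq_len(result$p_dfnc), drop = FALSE]
}

#' Flag super-Gaussian components
#'
#' Recomputes excess kurtosis on each joint source row and flags rows
#' exceeding the threshold. Only flagged (sparse/peaky) components are the
#' distributional family the logistic-Infomax model extracts; sub-Gaussian
#' rows are excluded from downstream validation.
#'
#' @param result a `fusion_result`.
#' @param kurtosis_threshold excess-kurtosis cutoff (default 0).
#' @return logical flag vector (also updated inside the returned result's
#'   `super_gaussian` field when assigned back).
#' @export
flag_super_gaussian <- function(result, kurtosis_threshold = 0) {
  apply(result$S, 1, excess_kurtosis) > kurtosis_threshold
}

#' Split stability of a fusion
#'
#' Partitions subjects into `n_folds` subsets, reruns the fusion within
#' each subset at the same model order, and greedily matches each subset's
#' components to the full-sample components by maximum absolute source
#' correlation (without replacement). Reports per-component and overall
#' mean/SD of the matched |r|.
#'
#' @param input a `fusion_input` (or plain matrix).
#' @param C model order.
#' @param n_folds number of subsets (default 3).
#' @param seed integer seed (partition and subset fusions).
#' @param full optional precomputed full-sample `fusion_result`.
#' @param ... passed to [infomax_jica()].
#' @return list with `per_component` data.frame (component, mean_r, sd_r),
#'   `matched_r` (C x n_folds matrix), `mean`, `sd`.
#' @export
split_stability <- function(input, C, n_folds = 3, seed = 1, full = NULL, ...) {
  X <- if (inherits(input, "fusion_input")) input$X else as.matrix(input)
  n <- nrow(X)
  if (floor(n / n_folds) <= C)
    stop("folds of ", floor(n / n_folds), " subjects are too small for C = ", C)
  if (is.null(full)) full <- infomax_jica(input, C, seed = seed, ...)
  fold <- with_substream(seed, 8192L, sample(rep_len(seq_len(n_folds), n)))
  matched <- matrix(NA_real_, C, n_folds)
  for (f in seq_len(n_folds)) {
    if (n_folds == 1) sub <- seq_len(n) else sub <- which(fold == f)
    seed_f <- if (n_folds == 1) seed else seed + f
    res_f <- infomax_jica(X[sub, , drop = FALSE], C, seed = seed_f, ...)
    mm <- match_sources(res_f$S, full$S)
    # report stability per full-sample component
    matched[mm$row_b, f] <- mm$abs_r
  }
  per_comp <- data.frame(component = seq_len(C),
                         mean_r = rowMeans(matched),
                         sd_r = apply(matched, 1, sd))
  list(per_component = per_comp, matched_r = matched,
       mean = mean(matched), sd = sd(as.vector(matched)))
}
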