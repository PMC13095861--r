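# dFNC state estimation: K-means over all windows, elbow selection of k,
# window assignment, subject-level state-average dFNC, and the covariate
# residualization used before fusion.

#' Stack windowed FNC series of many subjects
#'
#' @param wfnc_list list of [windowed_fnc()] results.
#' @return list with `windows` (all windows x n_pairs), `subject` (factor of
#'   subject ids per row), `row_map` (per-subject row indices).
#' @export
stack_windows <- function(wfnc_list) {
  npair <- unique(vapply(wfnc_list, function(w) ncol(w$z), 0L))
  stopifnot(length(npair) == 1)
  ids <- vapply(seq_along(wfnc_list), function(i) {
    s <- wfnc_list[[i]]$subject
    if (is.na(s)) paste0("subj", i) else s
  }, "")
  counts <- vapply(wfnc_list, function(w) nrow(w$z), 0L)
  windows <- do.call(rbind, lapply(wfnc_list, `[[`, "z"))
  subject <- rep(ids, counts)
  ends <- cumsum(counts)
  row_map <- lapply(seq_along(counts),
                    function(i) (ends[i] - counts[i] + 1):ends[i])
  names(row_map) <- ids
  list(windows = windows, subject = subject, row_map = row_map)
}

# k-means++ seeding (Arthur & Vassilvitskii): spread initial centers by
# sampling proportionally to squared distance from the nearest chosen center.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ], "-")^2)
  for (j in seq_len(k - 1)) {
    probs <- d2 / sum(d2)
    centers[j + 1, ] <- x[sample.int(n, 1, prob = probs), ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j + 1, ], "-")^2))
  }
  centers
}

run_kmeans_once <- function(x, k) {
  init <- kmeanspp_init(x, k)
  for (attempt in 1:10) {
    fit <- tryCatch(kmeans(x, centers = init, iter.max = 200),
                    warning = function(w) NULL, error = function(e) NULL)
    if (!is.null(fit) && all(fit$size > 0)) return(fit)
    init <- kmeanspp_init(x, k) # empty cluster or failure: reseed
  }
  stop("k-means produced an empty cluster in 10 restarts (k = ", k, ")")
}

#' Elbow of an inertia (or scree) curve by maximum second difference
#'
#' @param values inertia per candidate, ordered by increasing k.
#' @return index (into `values`) of the elbow; requires length >= 3.
#' @export
second_difference_elbow <- function(values) {
  stopifnot(length(values) >= 3)
  d2 <- diff(values, differences = 2) # values[i+2] - 2 values[i+1] + values[i]
  which.max(d2) + 1L                  # elbow at the middle point
}

#' Estimate dFNC states by K-means with elbow selection of k
#'
#' Runs K-means (k-means++ initialization, squared-Euclidean distance,
#' `replicates` restarts keeping the best inertia) for every k in
#' `k_range`; the number of states is the k maximizing the second
#' difference of the inertia curve (for a singleton `k_range` that k is
#' used directly), and the model is refit at the selected k.
#'
#' @param windows all-subject window matrix (rows = windows, columns =
#'   connectivity pairs), e.g. from [stack_windows()].
#' @param k_range candidate numbers of states; default `2:8`.
#' @param replicates K-means restarts per k; default 10.
#' @param seed integer seed; the fit is deterministic given it.
#' @return object of class `state_model`: `k`, `centroids` (k x n_pairs),
#'   `assignments` (per input window), `inertia` (named by k), `k_range`.
#' @export
fit_states <- function(windows, k_range = 2:8, replicates = 10, seed = 1) {
  windows <- as.matrix(windows)
  stopifnot(nrow(windows) >= 10 * max(k_range))
  k_range <- sort(unique(as.integer(k_range)))

  best_fit_for_k <- function(k, substream) {
    with_substream(seed, substream, {
      best <- NULL
      for (r in seq_len(replicates)) {
        fit <- run_kmeans_once(windows, k)
        if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
      }
      best
    })
  }

  fits <- lapply(seq_along(k_range),
                 function(i) best_fit_for_k(k_range[i], 1000L + i))
  inertia <- vapply(fits, `[[`, 0, "tot.withinss")
  names(inertia) <- k_range

  if (length(k_range) == 1) {
    sel <- 1L
  } else if (length(k_range) == 2) {
    sel <- 1L # no curvature information; keep the smaller k
  } else {
    sel <- second_difference_elbow(inertia)
  }
  fit <- fits[[sel]]
  structure(list(k = k_range[sel], centroids = fit$centers,
                 assignments = as.integer(fit$cluster),
                 inertia = inertia, k_range = k_range),
            class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("dFNC state model: k = %d (scanned k = %s)\n", x$k,
              paste(x$k_range, collapse = ", ")))
  cat("inertia:", paste(sprintf("%s=%.4g", names(x$inertia), x$inertia),
                        collapse = "  "), "\n")
  invisible(x)
}

#' Assign windows to the nearest state centroid
#'
#' Hard assignment by minimum Euclidean distance; ties break to the lowest
#' state index. Used both for discovery windows and for projecting a new
#' cohort's windows onto previously estimated centroids (never re-clustered).
#'
#' @param model a [fit_states()] result (or any list with a `centroids`
#'   matrix).
#' @param wfnc a [windowed_fnc()] result or a plain window matrix.
#' @return integer vector of state indices in `1:k`.
#' @export
assign_windows <- function(model, wfnc) {
  z <- if (inherits(wfnc, "wfnc")) wfnc$z else as.matrix(wfnc)
  cen <- model$centroids
  if (ncol(z) != ncol(cen))
    stop("pair dimension mismatch: windows have ", ncol(z),
         ", centroids have ", ncol(cen))
  # ||x - c||^2 = ||x||^2 - 2 x.c + ||c||^2; ||x||^2 constant per row.
  d <- -2 * z %*% t(cen)
  d <- sweep(d, 2, rowSums(cen^2), "+")
  as.integer(unname(apply(d, 1, which.min))) # first (lowest) index on ties
}

#' State-average dFNC of one subject in one state
#'
#' @param wfnc a [windowed_fnc()] result or window matrix for one subject.
#' @param assignments state index per window.
#' @param state state of interest.
#' @return mean pair vector over the subject's windows in that state, or
#'   `NULL` when the subject never visits it.
#' @export
state_average <- function(wfnc, assignments, state) {
  z <- if (inherits(wfnc, "wfnc")) wfnc$z else as.matrix(wfnc)
  stopifnot(length(assignments) == nrow(z))
  rows <- which(assignments == state)
  if (!length(rows)) return(NULL)
  colMeans(z[rows, , drop = FALSE])
}

#' Subject-by-state sa-dFNC matrices
#'
#' Averages each subject's windows within each state. Subjects that never
#' visit a state are omitted from that state's matrix, so sample sizes may
#' differ across states.
#'
#' @param wfnc_list list of per-subject [windowed_fnc()] results.
#' @param assignments_list matching list of per-window state assignments.
#' @param k number of states.
#' @return list of length `k`; element s is a matrix (visiting subjects x
#'   n_pairs) with subject ids as row names.
#' @export
sa_dfnc <- function(wfnc_list, assignments_list, k) {
  stopifnot(length(wfnc_list) == length(assignments_list))
  ids <- vapply(seq_along(wfnc_list), function(i) {
    s <- wfnc_list[[i]]$subject
    if (is.na(s)) paste0("subj", i) else s
  }, "")
  lapply(seq_len(k), function(s) {
    rows <- lapply(seq_along(wfnc_list), function(i)
      state_average(wfnc_list[[i]], assignments_list[[i]], s))
    keep <- !vapply(rows, is.null, TRUE)
    if (!any(keep)) {
      m <- matrix(numeric(0), 0, ncol(wfnc_list[[1]]$z))
      rownames(m) <- character(0)
      return(m)
    }
    m <- do.call(rbind, rows[keep])
    rownames(m) <- ids[keep]
    m
  })
}

#' Residualize features on covariates
#'
#' Per-feature ordinary least squares with an intercept; character/factor
#' covariates are dummy-coded dropping one level. Returns the residuals.
#' Used to remove age, sex and site from connectivity features and sex,
#' site and ancestry principal components from genotype dosages before
#' fusion.
#'
#' @param x subjects x features matrix (row names = subject ids, matched
#'   against `covariates$subject` when present).
#' @param covariates data.frame of covariates.
#' @param names covariate column names to regress out; default all columns
#'   except `subject`.
#' @return residual matrix, same shape and dimnames as `x`.
#' @export
residualize_features <- function(x, covariates, names = NULL) {
  x <- as.matrix(x)
  if (!is.null(covariates$subject) && !is.null(rownames(x))) {
    idx <- match(rownames(x), covariates$subject)
    if (anyNA(idx)) stop("covariates missing for subject(s): ",
                         paste(head(rownames(x)[is.na(idx)], 5), collapse = ", "))
    covariates <- covariates[idx, , drop = FALSE]
  }
  if (is.null(names)) names <- setdiff(colnames(covariates), "subject")
  if (!length(names)) return(sweep(x, 2, colMeans(x), "-"))
  miss <- setdiff(names, colnames(covariates))
  if (length(miss)) stop("unknown covariate(s): ", paste(miss, collapse = ", "))
  df <- covariates[, names, drop = FALSE]
  for (nm in names(df)) if (is.character(df[[nm]])) df[[nm]] <- factor(df[[nm]])
  mm <- stats::model.matrix(~ ., data = df)
  qrd <- qr(mm)
  if (qrd$rank < ncol(mm)) {
    bad <- colnames(mm)[qrd$pivot[(qrd$rank + 1):ncol(mm)]]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  res <- x - mm %*% qr.coef(qrd, x)
  dimnames(res) <- dimnames(x)
  res
}

#' Genotype principal components for population-stratification control
#'
#' Column-standardizes the dosage matrix (zero-variance SNPs dropped with a
#' warning), takes the SVD, and returns the top `n_pcs` left singular
#' vectors scaled by their singular values. Sign convention: within each
#' PC, the element of largest magnitude is positive.
#'
#' @param genotypes a `genotype_matrix` or plain dosage matrix.
#' @param n_pcs number of components (default 4).
#' @return subjects x n_pcs score matrix (columns `PC1`, ...).
#' @export
compute_genotype_pcs <- function(genotypes, n_pcs = 4) {
  g <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosage else as.matrix(genotypes)
  if (n_pcs == 0) {
    m <- matrix(numeric(0), nrow(g), 0)
    rownames(m) <- rownames(g)
    return(m)
  }
  stopifnot(n_pcs < min(dim(g)))
  sdv <- apply(g, 2, sd)
  if (any(sdv == 0)) {
    warning(sum(sdv == 0), " zero-variance SNP(s) dropped before PCA")
    g <- g[, sdv > 0, drop = FALSE]
    sdv <- sdv[sdv > 0]
  }
  gz <- sweep(sweep(g, 2, colMeans(g), "-"), 2, sdv, "/")
  s <- svd(gz, nu = n_pcs, nv = 0)
  scores <- s$u %*% diag(s$d[seq_len(n_pcs)], n_pcs)
  for (j in seq_len(n_pcs)) {
    if (scores[which.max(abs(scores[, j])), j] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(rownames(g), paste0("PC", seq_len(n_pcs)))
  scores
}
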