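# Independent-cohort validation: projection of discovery dFNC sources onto
# a new cohort's sa-dFNC features, covariate-controlled case-control
# testing with joint FDR, and partial correlations with cognitive and
# symptom scores.

#' Project discovery dFNC sources onto a validation cohort
#'
#' Computes `A_val = X_val %*% pinv(S_dfnc)` with the Moore-Penrose
#' pseudo-inverse, yielding per-subject loadings of the discovery
#' components in the validation cohort. `X_val` should be the validation
#' cohort's (covariate-residualized) sa-dFNC matrix for the same state and
#' pair legend as the discovery fusion.
#'
#' @param x_val validation subjects x n_pairs matrix.
#' @param s_dfnc discovery dFNC source block (C x n_pairs), e.g.
#'   `source_block(result, "dfnc")`.
#' @param state optional state index carried through.
#' @return object of class `projection_result`: `A_val` (subjects x C),
#'   `subject_ids`, `state`.
#' @export
project_dfnc <- function(x_val, s_dfnc, state = NA_integer_) {
  x_val <- as.matrix(x_val); s_dfnc <- as.matrix(s_dfnc)
  if (ncol(x_val) != ncol(s_dfnc))
    stop("pair mismatch: validation features have ", ncol(x_val),
         " pairs, sources have ", ncol(s_dfnc))
  A <- x_val %*% pinv(s_dfnc)
  colnames(A) <- rownames(s_dfnc)
  structure(list(A_val = A, subject_ids = rownames(x_val), state = state),
            class = "projection_result")
}

#' Case-control test of projected loadings
#'
#' Per component: residualizes the loading on the covariates (diagnosis
#' excluded from the design), then applies a pooled-variance two-sample
#' t-test between cases and controls with `df = n1 + n2 - 2` and effect
#' size `r^2 = t^2 / (t^2 + df)`, the share of loading variance explained
#' by the case-control difference.
#'
#' FDR correction is intentionally NOT applied here: collect the tests of
#' all parallel fusions and call [fdr_across_fusions()] so the
#' Benjamini-Hochberg family spans every component of every state.
#'
#' @param a_val loading matrix (subjects x C) or `projection_result`.
#' @param diagnosis 0/1 vector (1 = case), aligned to rows of `a_val`.
#' @param covariates optional data.frame of nuisance covariates (e.g. age,
#'   sex, site, mean framewise displacement) aligned the same way.
#' @param covariate_names columns of `covariates` to use; default all
#'   except `subject` and `diagnosis`.
#' @param welch use Welch's unequal-variance t instead of pooled (default
#'   `FALSE`).
#' @param state optional state index attached to the rows.
#' @return data.frame (state, comp, t, df, p, r2).
#' @export
group_difference <- function(a_val, diagnosis, covariates = NULL,
                             covariate_names = NULL, welch = FALSE,
                             state = NA_integer_) {
  if (inherits(a_val, "projection_result")) {
    if (is.na(state)) state <- a_val$state
    a_val <- a_val$A_val
  }
  a_val <- as.matrix(a_val)
  stopifnot(length(diagnosis) == nrow(a_val))
  diagnosis <- as.integer(diagnosis)
  if (length(unique(diagnosis)) < 2) stop("both groups required")
  if (min(table(diagnosis)) < 2) stop("each group needs n >= 2")
  if (!is.null(covariates)) {
    if (is.null(covariate_names))
      covariate_names <- setdiff(colnames(covariates), c("subject", "diagnosis"))
    a_val <- residualize_features(a_val, covariates, covariate_names)
  }
  cases <- diagnosis == 1L
  n1 <- sum(cases); n0 <- sum(!cases)
  res <- vapply(seq_len(ncol(a_val)), function(j) {
    x1 <- a_val[cases, j]; x0 <- a_val[!cases, j]
    if (welch) {
      tt <- stats::t.test(x1, x0, var.equal = FALSE)
      c(unname(tt$statistic), unname(tt$parameter))
    } else {
      sp2 <- ((n1 - 1) * var(x1) + (n0 - 1) * var(x0)) / (n1 + n0 - 2)
      t <- (mean(x1) - mean(x0)) / sqrt(sp2 * (1 / n1 + 1 / n0))
      c(t, n1 + n0 - 2)
    }
  }, numeric(2))
  t <- res[1, ]; df <- res[2, ]
  data.frame(state = state, comp = seq_len(ncol(a_val)), t = t, df = df,
             p = 2 * pt(-abs(t), df), r2 = t^2 / (t^2 + df))
}

#' Benjamini-Hochberg FDR across all parallel fusions
#'
#' Binds the per-state [group_difference()] tables and computes BH step-up
#' q-values jointly across every component of every fusion (one family),
#' flagging `q < alpha`.
#'
#' @param ... `group_difference()` data.frames (or a single list of them).
#' @param alpha significance level (default 0.05).
#' @return combined data.frame with added `q` and `significant` columns.
#' @export
fdr_across_fusions <- function(..., alpha = 0.05) {
  args <- list(...)
  if (length(args) == 1 && is.list(args[[1]]) && !is.data.frame(args[[1]]))
    args <- args[[1]]
  tab <- do.call(rbind, args)
  tab$q <- p.adjust(tab$p, method = "BH")
  tab$significant <- tab$q < alpha
  attr(tab, "alpha") <- alpha
  tab
}

#' Partial correlation of projected loadings with behavioral scores
#'
#' Residualizes both the loading and the score on the covariates (listwise
#' deletion of missing values), correlates the residuals, and reports a
#' two-sided p from the t distribution with `n - 2 - n_covariates` degrees
#' of freedom. P-values are reported uncorrected, as is conventional for
#' this descriptive association stage.
#'
#' @param a_val loading matrix (subjects x C) or `projection_result`.
#' @param scores data.frame or matrix of score columns aligned to `a_val`
#'   rows (e.g. cognitive domain scores, symptom subscales).
#' @param covariates optional covariate data.frame aligned the same way.
#' @param covariate_names columns of `covariates` to regress out.
#' @param subset optional logical vector restricting the analysis (e.g.
#'   patients only for symptom scores).
#' @param state optional state index.
#' @return data.frame (state, comp, measure, r, p, n).
#' @export
partial_association <- function(a_val, scores, covariates = NULL,
                                covariate_names = NULL, subset = NULL,
                                state = NA_integer_) {
  if (inherits(a_val, "projection_result")) {
    if (is.na(state)) state <- a_val$state
    a_val <- a_val$A_val
  }
  a_val <- as.matrix(a_val)
  scores <- as.data.frame(scores)
  stopifnot(nrow(scores) == nrow(a_val))
  if (!is.null(subset)) {
    a_val <- a_val[subset, , drop = FALSE]
    scores <- scores[subset, , drop = FALSE]
    if (!is.null(covariates)) covariates <- covariates[subset, , drop = FALSE]
  }
  if (!is.null(covariates) && is.null(covariate_names))
    covariate_names <- setdiff(colnames(covariates), c("subject", "diagnosis"))
  q <- if (is.null(covariates)) 0L else {
    df0 <- covariates[, covariate_names, drop = FALSE]
    sum(vapply(df0, function(v) if (is.character(v) || is.factor(v))
      length(unique(v)) - 1L else 1L, 0L))
  }
  out <- list()
  for (m in colnames(scores)) {
    ok <- stats::complete.cases(scores[[m]], a_val)
    if (!is.null(covariates))
      ok <- ok & stats::complete.cases(covariates[, covariate_names, drop = FALSE])
    n <- sum(ok)
    if (n < q + 3) stop("too few complete observations (", n, ") for measure ", m)
    y <- scores[[m]][ok]
    Aok <- a_val[ok, , drop = FALSE]
    if (!is.null(covariates)) {
      cov_ok <- covariates[ok, , drop = FALSE]
      cov_ok$subject <- NULL
      y <- as.vector(residualize_features(matrix(y), cov_ok, covariate_names))
      Aok <- residualize_features(Aok, cov_ok, covariate_names)
    }
    r <- as.vector(cor(Aok, y))
    dfree <- n - 2 - q
    t <- r * sqrt(dfree / (1 - r^2))
    out[[m]] <- data.frame(state = state, comp = seq_len(ncol(Aok)),
                           measure = m, r = r, p = 2 * pt(-abs(t), dfree), n = n)
  }
  do.call(rbind, out)
}
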