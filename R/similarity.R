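# Across-state component matching: quantifies how much each joint
# component's SNP and dFNC elements recur across the parallel per-state
# fusions (state-invariant) or not (state-variant).

#' Match components across parallel fusions
#'
#' For each component of each fusion and each modality sub-vector, computes
#' the absolute Pearson correlation to every component of every other
#' fusion over that modality's feature columns. The best counterpart per
#' other fusion is the argmax (ties break to the lowest component index);
#' matching is directional and with replacement. The across-state
#' similarity of a component is the mean of its best |r| values over the
#' other fusions, per modality. The headline counterpart (`state_similar`,
#' `comp_similar`) is chosen by combined similarity (mean of the SNP and
#' dFNC |r|).
#'
#' @param results list of `fusion_result` objects (one per state) sharing
#'   the same feature spaces.
#' @return object of class `component_match_table`: data.frame with one
#'   row per (state, component): best counterpart, `snp_similarity`,
#'   `dfnc_similarity` (across-state means), and per-other-state matches
#'   in attribute `detail`.
#' @export
match_components <- function(results) {
  stopifnot(length(results) >= 2)
  p_snp <- unique(vapply(results, function(r) as.integer(r$p_snp), 0L))
  p_dfnc <- unique(vapply(results, function(r) as.integer(r$p_dfnc), 0L))
  if (length(p_snp) != 1 || length(p_dfnc) != 1)
    stop("fusions have mismatched feature spaces: p_snp in {",
         paste(p_snp, collapse = ","), "}, p_dfnc in {",
         paste(p_dfnc, collapse = ","), "}")
  fid <- lapply(results, `[[`, "feature_ids")
  if (!all(vapply(fid, identical, TRUE, fid[[1]])))
    stop("fusions have differing feature ids; same SNP panel and pair legend required")
  n_state <- length(results)
  states <- vapply(seq_len(n_state), function(i) {
    s <- results[[i]]$state
    if (is.na(s)) i else s
  }, 0L)

  rows <- list()
  detail <- list()
  for (a in seq_len(n_state)) {
    Sa_snp <- source_block(results[[a]], "snp")
    Sa_dfnc <- source_block(results[[a]], "dfnc")
    Ca <- results[[a]]$C
    best_snp <- best_dfnc <- best_comb <- array(
      NA_real_, c(Ca, n_state), dimnames = list(NULL, states))
    best_idx <- array(NA_integer_, c(Ca, n_state))
    for (b in seq_len(n_state)) {
      if (b == a) next
      r_snp <- abs(cor(t(Sa_snp), t(source_block(results[[b]], "snp"))))
      r_dfnc <- abs(cor(t(Sa_dfnc), t(source_block(results[[b]], "dfnc"))))
      best_snp[, b] <- apply(r_snp, 1, max)
      best_dfnc[, b] <- apply(r_dfnc, 1, max)
      comb <- (r_snp + r_dfnc) / 2
      best_idx[, b] <- apply(comb, 1, which.max) # first index on ties
      best_comb[, b] <- apply(comb, 1, max)
    }
    others <- setdiff(seq_len(n_state), a)
    overall <- apply(best_comb[, others, drop = FALSE], 1, which.max)
    rows[[a]] <- data.frame(
      state = states[a], comp = seq_len(Ca),
      state_similar = states[others][overall],
      comp_similar = best_idx[cbind(seq_len(Ca), others[overall])],
      snp_similarity = rowMeans(best_snp[, others, drop = FALSE]),
      dfnc_similarity = rowMeans(best_dfnc[, others, drop = FALSE]),
      combined_similarity = rowMeans(best_comb[, others, drop = FALSE]))
    detail[[a]] <- list(best_snp = best_snp, best_dfnc = best_dfnc,
                        best_idx = best_idx)
  }
  out <- do.call(rbind, rows)
  attr(out, "detail") <- detail
  class(out) <- c("component_match_table", class(out))
  out
}

#' Classify components along the state-invariant / state-variant axis
#'
#' @param table a [match_components()] result.
#' @param invariant_cutoff mean similarity at or above which a component's
#'   modality element is called state-invariant (default 0.85).
#' @param variant_cutoff mean similarity at or below which it is called
#'   state-variant (default 0.40); everything between is "intermediate".
#' @return the table with added `snp_class` and `dfnc_class` columns;
#'   cutoffs recorded in attributes `invariant_cutoff`/`variant_cutoff`.
#' @export
classify_variability <- function(table, invariant_cutoff = 0.85,
                                 variant_cutoff = 0.40) {
  stopifnot(variant_cutoff < invariant_cutoff,
            invariant_cutoff <= 1, variant_cutoff >= 0)
  lab <- function(s) ifelse(s >= invariant_cutoff, "invariant",
                            ifelse(s <= variant_cutoff, "variant", "intermediate"))
  table$snp_class <- lab(table$snp_similarity)
  table$dfnc_class <- lab(table$dfnc_similarity)
  attr(table, "invariant_cutoff") <- invariant_cutoff
  attr(table, "variant_cutoff") <- variant_cutoff
  table
}

#' Sorted similarity curves per state and modality
#'
#' Descending across-state similarity of each fusion's components,
#' exported for plotting the invariant-to-variant spectrum.
#'
#' @param table a [match_components()] result.
#' @return data.frame (state, rank, snp_similarity, dfnc_similarity).
#' @export
similarity_curves <- function(table) {
  do.call(rbind, lapply(split(table, table$state), function(df) {
    data.frame(state = df$state[1], rank = seq_len(nrow(df)),
               snp_similarity = sort(df$snp_similarity, decreasing = TRUE),
               dfnc_similarity = sort(df$dfnc_similarity, decreasing = TRUE))
  }))
}
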