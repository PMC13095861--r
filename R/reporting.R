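# Interpretation layer: top-weighted features of significant components,
# gene-overlap ratios, domain-level connectivity summaries, and the tabular
# report files.

#' Top-weighted SNPs and connectivity pairs of a component
#'
#' Z-scores each modality's source sub-vector separately (mean/SD over that
#' block's columns) and retains features with `|z|` beyond the threshold.
#' Pairs are annotated with ICN labels and functional domains from the
#' legend; SNPs with genes from the user-supplied annotation map, when
#' provided.
#'
#' @param result a `fusion_result`.
#' @param component component index.
#' @param z_threshold retention threshold on |z| (default 3).
#' @param icn_legend optional data.frame (`index`, `label`, `domain`) for
#'   pair annotation; required for annotated pairs.
#' @param snp_annotation optional data.frame (`snp`, `chromosome`,
#'   `position`, `gene`).
#' @return object of class `top_feature_set`: list with `snps` (data.frame
#'   snp, z, gene, chromosome, position), `pairs` (data.frame pair, i, j,
#'   label_i, label_j, domain_i, domain_j, weight, z), `threshold`,
#'   `state`, `component`.
#' @export
top_features <- function(result, component, z_threshold = 3,
                         icn_legend = NULL, snp_annotation = NULL) {
  stopifnot(component >= 1, component <= result$C)
  zblock <- function(v) {
    s <- sd(v)
    if (s == 0) {
      warning("constant source sub-vector; returning no features")
      return(rep(0, length(v)))
    }
    (v - mean(v)) / s
  }
  s_snp <- source_block(result, "snp")[component, ]
  s_dfnc <- source_block(result, "dfnc")[component, ]
  z_snp <- zblock(s_snp)
  z_dfnc <- zblock(s_dfnc)

  keep_s <- which(abs(z_snp) > z_threshold)
  snp_ids <- names(s_snp)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_along(s_snp))
  snps <- data.frame(snp = snp_ids[keep_s], z = z_snp[keep_s],
                     weight = s_snp[keep_s], row.names = NULL)
  if (!is.null(snp_annotation)) {
    m <- match(snps$snp, snp_annotation$snp)
    snps$gene <- snp_annotation$gene[m]
    snps$chromosome <- snp_annotation$chromosome[m]
    snps$position <- snp_annotation$position[m]
  } else if (nrow(snps)) {
    warning("no SNP annotation map provided; gene column left empty")
    snps$gene <- NA_character_
  } else snps$gene <- character(0)

  keep_d <- which(abs(z_dfnc) > z_threshold)
  n_icns <- (1 + sqrt(1 + 8 * length(s_dfnc))) / 2
  ij <- if (length(keep_d)) pair_unrank(keep_d, n_icns) else
    data.frame(i = integer(), j = integer())
  pairs <- data.frame(pair = keep_d, i = ij$i, j = ij$j,
                      weight = s_dfnc[keep_d], z = z_dfnc[keep_d],
                      row.names = NULL)
  if (!is.null(icn_legend)) {
    pairs$label_i <- icn_legend$label[match(pairs$i, icn_legend$index)]
    pairs$label_j <- icn_legend$label[match(pairs$j, icn_legend$index)]
    pairs$domain_i <- icn_legend$domain[match(pairs$i, icn_legend$index)]
    pairs$domain_j <- icn_legend$domain[match(pairs$j, icn_legend$index)]
  }
  structure(list(snps = snps, pairs = pairs, threshold = z_threshold,
                 state = result$state, component = component),
            class = "top_feature_set")
}

#' @export
print.top_feature_set <- function(x, ...) {
  cat(sprintf("Top features (|z| > %g)%s, component %d: %d SNPs, %d pairs\n",
              x$threshold,
              if (!is.na(x$state)) paste0(", state ", x$state) else "",
              x$component, nrow(x$snps), nrow(x$pairs)))
  invisible(x)
}

#' Jaccard overlap ratio of two feature sets
#'
#' `|A intersect B| / |A union B|`, reported as a percentage. The overlap
#' coefficient `|A intersect B| / min(|A|, |B|)` is available behind
#' `method = "overlap"`.
#'
#' @param set_a,set_b character vectors (gene symbols or SNP ids).
#' @param method `"jaccard"` (default) or `"overlap"`.
#' @return percentage in `[0, 100]`; `NA` when both sets are empty.
#' @export
overlap_ratio <- function(set_a, set_b, method = c("jaccard", "overlap")) {
  method <- match.arg(method)
  a <- unique(set_a[!is.na(set_a)]); b <- unique(set_b[!is.na(set_b)])
  if (!length(a) && !length(b)) return(NA_real_)
  inter <- length(intersect(a, b))
  denom <- switch(method,
                  jaccard = length(union(a, b)),
                  overlap = min(length(a), length(b)))
  if (denom == 0) return(NA_real_)
  100 * inter / denom
}

#' Domain-level summary of retained connectivity pairs
#'
#' Aggregates a component's retained pairs into domain x domain counts
#' split by weight sign, and flags hub ICNs (ICNs participating in at
#' least `hub_fraction` of the retained pairs).
#'
#' @param pairs the `pairs` data.frame of a [top_features()] result,
#'   annotated with `domain_i`/`domain_j` (or pass `icn_legend`).
#' @param icn_legend optional legend to (re-)annotate from.
#' @param hub_fraction participation fraction defining a hub (default 0.5).
#' @return list with `counts` (data.frame domain_a, domain_b, positive,
#'   negative) and `hubs` (data.frame icn, label, n_pairs, fraction).
#' @export
domain_summary <- function(pairs, icn_legend = NULL, hub_fraction = 0.5) {
  if (!is.null(icn_legend)) {
    pairs$domain_i <- icn_legend$domain[match(pairs$i, icn_legend$index)]
    pairs$domain_j <- icn_legend$domain[match(pairs$j, icn_legend$index)]
    pairs$label_i <- icn_legend$label[match(pairs$i, icn_legend$index)]
    pairs$label_j <- icn_legend$label[match(pairs$j, icn_legend$index)]
  }
  if (nrow(pairs) && (anyNA(pairs$domain_i) || anyNA(pairs$domain_j)))
    stop("unlabeled ICN(s) in: ",
         paste(unique(c(pairs$i[is.na(pairs$domain_i)],
                        pairs$j[is.na(pairs$domain_j)])), collapse = ", "))
  if (!nrow(pairs)) {
    return(list(counts = data.frame(domain_a = character(), domain_b = character(),
                                    positive = integer(), negative = integer()),
                hubs = data.frame(icn = integer(), n_pairs = integer(),
                                  fraction = numeric())))
  }
  # unordered domain pair key
  da <- pmin(pairs$domain_i, pairs$domain_j)
  db <- pmax(pairs$domain_i, pairs$domain_j)
  key <- paste(da, db, sep = "~")
  counts <- do.call(rbind, lapply(split(seq_len(nrow(pairs)), key), function(idx) {
    data.frame(domain_a = da[idx[1]], domain_b = db[idx[1]],
               positive = sum(pairs$weight[idx] > 0),
               negative = sum(pairs$weight[idx] < 0))
  }))
  rownames(counts) <- NULL
  part <- table(c(pairs$i, pairs$j))
  frac <- as.numeric(part) / nrow(pairs)
  hubs <- data.frame(icn = as.integer(names(part)), n_pairs = as.integer(part),
                     fraction = frac)[frac >= hub_fraction, , drop = FALSE]
  rownames(hubs) <- NULL
  list(counts = counts, hubs = hubs)
}

#' Write the run-level report files
#'
#' Writes a Manhattan-style SNP table (ordered by chromosome and position,
#' unannotated SNPs last), a connectogram edge list, the sorted
#' across-state similarity curves, the merged component results table, and
#' a key-value run summary.
#'
#' @param outdir output directory.
#' @param results_table merged per-component table (similarity + validation
#'   columns), or `NULL`.
#' @param top_sets list of [top_features()] results for the significant
#'   components (may be empty).
#' @param match_table optional [match_components()] table for the
#'   similarity curves.
#' @param params named list logged into the run summary.
#' @return invisibly, the vector of files written.
#' @export
render_reports <- function(outdir, results_table = NULL, top_sets = list(),
                           match_table = NULL, params = list()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f) {
    write.table(x, file.path(outdir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
    f
  }
  written <- character(0)

  snp_rows <- do.call(rbind, lapply(top_sets, function(ts) {
    if (!nrow(ts$snps)) return(NULL)
    cbind(state = ts$state, comp = ts$component, ts$snps)
  }))
  if (!is.null(snp_rows) && nrow(snp_rows)) {
    ord <- order(is.na(snp_rows$chromosome), snp_rows$chromosome,
                 snp_rows$position)
    written <- c(written, tsv(snp_rows[ord, ], "manhattan_snps.tsv"))
  } else written <- c(written, tsv(data.frame(state = integer(), comp = integer(),
                                              snp = character(), z = numeric()),
                                   "manhattan_snps.tsv"))

  edge_rows <- do.call(rbind, lapply(top_sets, function(ts) {
    if (!nrow(ts$pairs)) return(NULL)
    cbind(state = ts$state, comp = ts$component, ts$pairs)
  }))
  if (is.null(edge_rows))
    edge_rows <- data.frame(state = integer(), comp = integer(),
                            pair = integer(), i = integer(), j = integer(),
                            weight = numeric(), z = numeric())
  written <- c(written, tsv(edge_rows, "connectogram_edges.tsv"))

  if (!is.null(match_table))
    written <- c(written, tsv(similarity_curves(match_table),
                              "similarity_curves.tsv"))
  if (!is.null(results_table))
    written <- c(written, tsv(results_table, "component_results.tsv"))

  n_sig <- length(top_sets)
  summary_lines <- c(
    sprintf("significant_components\t%d", n_sig),
    if (n_sig == 0) "banner\t0 components passed validation",
    vapply(names(params), function(k) sprintf("%s\t%s", k,
                                              paste(params[[k]], collapse = ",")), ""))
  writeLines(summary_lines, file.path(outdir, "run_summary.tsv"))
  written <- c(written, "run_summary.tsv")
  invisible(written)
}
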