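# Upper-triangle pair indexing for FNC vectors. Connectivity between n ICNs
# is stored as a vector of the n*(n-1)/2 unique pairs (i < j), row-major:
# (1,2), (1,3), ..., (1,n), (2,3), ...

#' Number of unique connectivity pairs for n ICNs
#'
#' @param n_icns number of intrinsic connectivity networks (nodes).
#' @return `n_icns * (n_icns - 1) / 2`. 53 ICNs give 1378 pairs.
#' @export
n_fnc_pairs <- function(n_icns) {
  stopifnot(n_icns >= 0)
  n_icns * (n_icns - 1) / 2
}

#' Pair index legend
#'
#' Enumerates ICN pairs (i < j) in row-major upper-triangle order, the
#' storage order of every FNC vector in this package.
#'
#' @param n_icns number of ICNs.
#' @return data.frame with columns `pair` (rank), `i`, `j`.
#' @export
pair_index <- function(n_icns) {
  if (n_icns < 2) return(data.frame(pair = integer(), i = integer(), j = integer()))
  ij <- which(upper.tri(matrix(0, n_icns, n_icns)), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  data.frame(pair = seq_len(nrow(ij)), i = ij[, 1], j = ij[, 2])
}

#' Rank of a pair (i, j) in the FNC vector
#'
#' @param i,j ICN indices with `i < j` (1-based).
#' @param n_icns number of ICNs.
#' @return 1-based position in the pair vector.
#' @export
pair_rank <- function(i, j, n_icns) {
  stopifnot(all(i >= 1), all(j > i), all(j <= n_icns))
  (i - 1) * n_icns - i * (i - 1) / 2 + (j - i)
}

#' Inverse of [pair_rank()]
#'
#' @param k 1-based pair rank(s).
#' @param n_icns number of ICNs.
#' @return data.frame with columns `i`, `j`.
#' @export
pair_unrank <- function(k, n_icns) {
  stopifnot(all(k >= 1), all(k <= n_fnc_pairs(n_icns)))
  i <- integer(length(k)); j <- integer(length(k))
  for (idx in seq_along(k)) {
    kk <- k[idx]
    ii <- 1
    while (kk > n_icns - ii) {
      kk <- kk - (n_icns - ii)
      ii <- ii + 1
    }
    i[idx] <- ii
    j[idx] <- ii + kk
  }
  data.frame(i = i, j = j)
}

#' Assemble a symmetric matrix from an FNC pair vector
#'
#' @param v pair vector of length `n_fnc_pairs(n_icns)`.
#' @param n_icns number of ICNs.
#' @param diag value placed on the diagonal (default 1).
#' @return symmetric `n_icns x n_icns` matrix.
#' @export
pairs_to_matrix <- function(v, n_icns, diag = 1) {
  stopifnot(length(v) == n_fnc_pairs(n_icns))
  m <- matrix(0, n_icns, n_icns)
  m[t(upper.tri(m))] <- 0 # keep dims
  idx <- pair_index(n_icns)
  m[cbind(idx$i, idx$j)] <- v
  m <- m + t(m)
  diag(m) <- diag
  m
}

#' Extract the FNC pair vector from a symmetric matrix
#'
#' @param m symmetric matrix.
#' @return upper-triangle values in row-major pair order.
#' @export
matrix_to_pairs <- function(m) {
  n <- nrow(m)
  idx <- pair_index(n)
  m[cbind(idx$i, idx$j)]
}
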