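# Shared fixture builders. Everything is generated in code at test time.

laplace_mat <- function(n, p) {
  matrix((rexp(n * p) - rexp(n * p)) / sqrt(2), n, p)
}

# Planted ICA problem: X = A0 S0 (+ noise). Returns the pieces.
planted_ica <- function(n = 300, C = 3, p = 1000, noise_sd = 0, seed = 1) {
  set.seed(seed)
  S0 <- laplace_mat(C, p)
  A0 <- matrix(rnorm(n * C), n, C)
  X <- A0 %*% S0
  if (noise_sd > 0) X <- X + matrix(rnorm(n * p, sd = noise_sd), n, p)
  list(X = X, A0 = A0, S0 = S0)
}

# Well-separated 2-D clusters for K-means checks.
planted_clusters <- function(n_per = 100, seed = 1) {
  set.seed(seed)
  cen <- matrix(c(0, 0, 6, 6, -6, 6), 3, 2, byrow = TRUE)
  x <- cen[rep(1:3, each = n_per), ] + matrix(rnorm(2 * 3 * n_per, sd = 0.4),
                                              3 * n_per, 2)
  list(x = x, centers = cen)
}

# Tapered Pearson correlation z-vector, the independent oracle for
# windowed_fnc at vanishing penalty.
tapered_cor_z <- function(xw, taper) {
  mu <- colSums(xw * taper)
  xc <- sweep(xw, 2, mu, "-") * sqrt(taper)
  S <- crossprod(xc) / (1 - sum(taper^2))
  R <- S / tcrossprod(sqrt(diag(S)))
  fisher_z(matrix_to_pairs(R))
}

# Small default study used by several integration tests.
tiny_design <- function(...) {
  synthetic_design(n_subjects = 40, n_snps = 60, n_icns = 6,
                   n_timepoints = 250, k_states = 3, n_components = 3,
                   seed = 7, ...)
}
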