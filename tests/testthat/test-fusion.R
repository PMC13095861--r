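test_that("modality balancing equalizes block energy and drops dead features", {
  set.seed(1)
  a <- matrix(rnorm(50 * 40), 50, 40)
  b <- matrix(rnorm(50 * 40), 50, 40)
  inp <- balance_and_concatenate(a, b)
  ns <- norm(inp$X[, seq_len(inp$p_snp)], "F")
  nd <- norm(inp$X[, inp$p_snp + seq_len(inp$p_dfnc)], "F")
  expect_lt(abs(ns - nd) / nd, 0.05)

  a2 <- a; a2[, 3] <- 7
  expect_warning(inp2 <- balance_and_concatenate(a2, b), "zero-variance")
  expect_equal(inp2$p_snp, 39)

  raw <- suppressWarnings(balance_and_concatenate(a, b, balance = FALSE))
  expect_equal(apply(raw$X, 2, sd), rep(1, 80), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("scree knee finds a planted low-rank dimension", {
  set.seed(2)
  r <- 6
  X <- matrix(rnorm(200 * r), 200, r) %*% matrix(rnorm(r * 300) * 4, r, 300) +
    matrix(rnorm(200 * 300), 200, 300)
  ev <- covariance_scree(X)
  expect_equal(scree_knee(ev), r, tolerance = 1)
})

test_that("the shared model order is the median knee, raised to a variance floor", {
  expect_equal(model_order_from_knees(c(35, 40, 39, 33, 33)), 35)
  expect_equal(model_order_from_knees(c(3, 5, 9), floor_variance = 0), 5)
  ev <- c(10, 8, 6, 4, 2, 1, 1, 1) # cumulative fractions: .30 .55 .73 .85 .91 ...
  expect_equal(model_order_from_knees(c(2, 2), floor_variance = 0.9,
                                      floor_screes = list(ev)), 5)
  expect_error(model_order_from_knees(2, floor_variance = 0.999999,
                                      floor_screes = list(c(1, 1 - 1e-12))),
               NA) # reachable floors never error
})

test_that("Infomax recovers noiseless planted super-Gaussian sources", {
  pi0 <- planted_ica(n = 300, C = 3, p = 1000, seed = 3)
  res <- infomax_jica(pi0$X, 3, seed = 1)
  expect_true(res$converged)
  mm <- match_sources(res$S, pi0$S0)
  expect_gt(mean(mm$abs_r), 0.99)
  # ICA ambiguity: permuted and sign-flipped planted sources match equally
  S_perm <- pi0$S0[c(3, 1, 2), ] * c(-1, 1, -1)
  mm2 <- match_sources(res$S, S_perm)
  expect_equal(sort(mm$abs_r), sort(mm2$abs_r), tolerance = 1e-10)
})

test_that("components are stable across restart seeds on noisy data", {
  pi0 <- planted_ica(n = 300, C = 3, p = 800, noise_sd = 1, seed = 4)
  r1 <- infomax_jica(pi0$X, 3, seed = 11)
  r2 <- infomax_jica(pi0$X, 3, seed = 77)
  mm <- match_sources(r1$S, r2$S)
  expect_gt(mean(mm$abs_r), 0.9)
})

test_that("the factorization reconstructs the rank-C PCA projection", {
  set.seed(5)
  X <- matrix(rnorm(80 * 200), 80, 200)
  res <- infomax_jica(X, 10, seed = 2)
  Xc <- sweep(X, 2, colMeans(X))
  pca_rec <- Xc %*% res$pca$v %*% t(res$pca$v)
  expect_lt(norm(res$A %*% res$S - pca_rec, "F") / norm(pca_rec, "F"), 1e-6)
  # tail invariant: residual energy equals the discarded eigenvalue mass
  sv <- svd(Xc, nu = 0, nv = 0)$d^2
  expect_equal(norm(Xc - pca_rec, "F")^2, sum(sv[-(1:10)]),
               tolerance = 1e-8 * sum(sv))
  # A is exactly X S+ by construction
  expect_equal(res$A, Xc %*% pinv(res$S), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("source rows are mutually uncorrelated and positively skewed", {
  pi0 <- planted_ica(n = 250, C = 4, p = 1200, noise_sd = 0.3, seed = 6)
  res <- infomax_jica(pi0$X, 4, seed = 3)
  cc <- cor(t(res$S))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)
  skew <- apply(res$S, 1, function(v) mean((v - mean(v))^3) / sd(v)^3)
  expect_true(all(skew >= 0))
})

test_that("model order above the data rank is refused", {
  set.seed(7)
  X <- matrix(rnorm(30 * 5), 30, 5) %*% matrix(rnorm(5 * 100), 5, 100)
  expect_error(infomax_jica(X, 10, seed = 1), "rank")
  expect_error(infomax_jica(X, 40, seed = 1), "below the subject count")
})

test_that("super-Gaussian flagging separates Laplace from Gaussian sources", {
  set.seed(8)
  fake <- list(S = rbind(laplace_mat(1, 10000),
                         matrix(rnorm(10000), 1)))
  flags <- flag_super_gaussian(fake, 0.2)
  expect_true(flags[1])
  expect_false(flags[2])
  gauss_not_flagged <- vapply(1:20, function(s) {
    set.seed(100 + s)
    excess_kurtosis(rnorm(1e4)) <= 0.2
  }, TRUE)
  expect_gte(mean(gauss_not_flagged), 0.95)
  expect_true(all(flag_super_gaussian(fake, -10)))
})

test_that("split stability is near-perfect on noiseless data and exact for one fold", {
  pi0 <- planted_ica(n = 360, C = 3, p = 600, seed = 9)
  st <- split_stability(pi0$X, 3, n_folds = 3, seed = 2)
  expect_gt(st$mean, 0.95)
  expect_equal(dim(st$matched_r), c(3, 3))
  st1 <- split_stability(pi0$X, 3, n_folds = 1, seed = 2)
  expect_equal(as.vector(st1$matched_r), rep(1, 3), tolerance = 1e-8)
  expect_error(split_stability(pi0$X, 3, n_folds = 200, seed = 2), "too small")
})
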