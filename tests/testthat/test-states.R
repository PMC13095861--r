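test_that("elbow selection recovers the planted cluster count", {
  pc <- planted_clusters(120, seed = 2)
  m <- fit_states(pc$x, k_range = 2:6, replicates = 5, seed = 1)
  expect_equal(m$k, 3)
  # every planted center has an estimated centroid within a small radius
  d <- vapply(seq_len(3), function(i)
    min(sqrt(rowSums(sweep(m$centroids, 2, pc$centers[i, ], "-")^2))), 0)
  expect_lt(max(d), 0.2)
})

test_that("a singleton k range bypasses elbow logic", {
  pc <- planted_clusters(50)
  m <- fit_states(pc$x, k_range = 2, replicates = 3, seed = 1)
  expect_equal(m$k, 2)
  expect_equal(length(m$inertia), 1)
})

test_that("duplicating every window leaves the centroids unchanged", {
  pc <- planted_clusters(80, seed = 5)
  m1 <- fit_states(pc$x, k_range = 3, replicates = 5, seed = 9)
  m2 <- fit_states(rbind(pc$x, pc$x), k_range = 3, replicates = 5, seed = 9)
  o1 <- m1$centroids[order(m1$centroids[, 1]), ]
  o2 <- m2$centroids[order(m2$centroids[, 1]), ]
  expect_equal(o1, o2, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("assignment is idempotent on centroids and ties break low", {
  pc <- planted_clusters(60, seed = 3)
  m <- fit_states(pc$x, k_range = 3, replicates = 3, seed = 2)
  expect_equal(assign_windows(m, m$centroids), 1:3)
  tie <- list(centroids = matrix(c(1, 0, 3, 0, 1, 0), 3, 2, byrow = TRUE))
  expect_equal(assign_windows(tie, matrix(c(1, 0), 1)), 1L) # rows 1 and 3 tie
  expect_equal(assign_windows(tie, matrix(c(2, 0), 1)), 1L) # equidistant 1/2/3
  expect_error(assign_windows(m, matrix(0, 2, 5)), "dimension mismatch")
})

test_that("state averages are per-state means and absent states drop out", {
  z <- matrix(1:12, 3, 4)
  expect_equal(state_average(z, c(1, 1, 2), 1), colMeans(z[1:2, ]))
  expect_null(state_average(z, c(1, 1, 2), 3))
  expect_equal(state_average(z, c(2, 2, 2), 2), colMeans(z))
})

test_that("sa-dFNC respects visit bookkeeping and the convex hull", {
  set.seed(10)
  wfs <- lapply(1:3, function(i)
    structure(list(z = matrix(rnorm(20 * 4), 20, 4), subject = paste0("P", i)),
              class = "wfnc"))
  asg <- list(rep(1:2, 10), rep(2L, 20), sample(1:3, 20, replace = TRUE))
  sa <- sa_dfnc(wfs, asg, 3)
  expect_equal(rownames(sa[[1]]), c("P1", "P3"))   # P2 never visits state 1
  expect_equal(rownames(sa[[3]]), "P3")
  # partition: visit counts per subject sum to the window count
  expect_equal(sum(vapply(1:3, function(s) sum(asg[[3]] == s), 0L)), 20L)
  # convex hull per coordinate
  for (s in 1:2) {
    v <- state_average(wfs[[1]], asg[[1]], s)
    sub <- wfs[[1]]$z[asg[[1]] == s, ]
    expect_true(all(v >= apply(sub, 2, min) & v <= apply(sub, 2, max)))
  }
})

test_that("residualization removes modeled covariates and only those", {
  set.seed(11)
  n <- 120
  cov <- data.frame(subject = sprintf("S%03d", 1:n),
                    age = rnorm(n, 50, 10),
                    site = sample(c("a", "b", "c"), n, replace = TRUE))
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(cov$subject, NULL))
  x[, 2] <- 2 * cov$age
  res <- residualize_features(x, cov, c("age", "site"))
  expect_lt(max(abs(res[, 2])), 1e-8)                 # exact fit removed
  # a covariate exactly orthogonal to the feature leaves it centered but intact
  f <- rnorm(n)
  cov2 <- data.frame(subject = cov$subject, c = rnorm(n))
  cov2$c <- resid(lm(cov2$c ~ f))
  r2 <- residualize_features(matrix(f, dimnames = list(cov$subject, NULL)),
                             cov2, "c")
  expect_equal(as.vector(r2), f - mean(f), tolerance = 1e-8)
  # 3-level site gives 2 dummy columns + intercept + age = 4-column design
  mm <- stats::model.matrix(~ age + factor(site), cov)
  expect_equal(ncol(mm), 4)
  # collinear design errors with the offending columns named
  cov$age2 <- cov$age
  expect_error(residualize_features(x, cov, c("age", "age2")), "collinear")
})

test_that("genotype PCs separate planted ancestry clusters and are orthogonal", {
  set.seed(12)
  n <- 200; p <- 150
  anc <- rep(0:1, each = n / 2)
  freq1 <- runif(p, 0.1, 0.5)
  freq2 <- pmin(0.5, pmax(0.05, freq1 + sample(c(-1, 1), p, TRUE) * 0.2))
  g <- t(vapply(seq_len(n), function(i) {
    f <- if (anc[i] == 0) freq1 else freq2
    rbinom(p, 2, f)
  }, numeric(p)))
  pcs <- compute_genotype_pcs(g, 4)
  expect_gt(abs(cor(pcs[, 1], anc)), 0.9)
  cc <- crossprod(sweep(pcs, 2, colMeans(pcs)))
  expect_lt(max(abs(cc[upper.tri(cc)])) / min(diag(cc)), 1e-8)
  expect_equal(ncol(compute_genotype_pcs(g, 0)), 0)
  g[, 1] <- 1
  expect_warning(compute_genotype_pcs(g, 2), "zero-variance")
})
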