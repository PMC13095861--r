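test_that("taper weights are normalized, symmetric, positive, peaked centrally", {
  w <- make_taper(20, 3)
  expect_equal(sum(w), 1)
  expect_equal(w, rev(w))
  expect_true(all(w > 0))
  expect_equal(length(w), 20 + 2 * ceiling(9))
  expect_equal(which.max(w), ceiling(length(w) / 2))
  # direct convolution oracle
  half <- ceiling(9)
  kern <- exp(-0.5 * ((-half):half / 3)^2)
  ora <- as.vector(stats::filter(c(rep(0, half), rep(1, 20), rep(0, half)),
                                 kern / sum(kern), sides = 2, circular = TRUE))
  expect_equal(w, ora / sum(ora), tolerance = 1e-10)
})

test_that("a vanishing Gaussian sigma recovers the rectangular window", {
  expect_equal(make_taper(20, 0), rep(1 / 20, 20))
  w <- make_taper(16, 1e-9)
  expect_equal(sum(w), 1)
})

test_that("detrending annihilates linear ramps and despiking clips outliers", {
  set.seed(1)
  nt <- 300
  ramp <- 3 * seq_len(nt)
  noise <- rnorm(nt)
  out <- postprocess_timecourses(cbind(ramp + noise, rnorm(nt)), 0.735)
  # the ramp contributes nothing: residual uncorrelated with time
  expect_lt(abs(cor(out[, 1], seq_len(nt))), 0.1)

  x <- rnorm(nt)
  x[150] <- median(x) + 100 * mad(x)
  m <- median(x); s <- mad(x)
  X <- cbind(x, rnorm(nt))
  Xd <- X - cbind(1, seq_len(nt)) %*% qr.coef(qr(cbind(1, seq_len(nt))), X)
  # check the clipping contract on the despike step in isolation
  clipped <- pmin(pmax(Xd[, 1], median(Xd[, 1]) - 4 * mad(Xd[, 1])),
                  median(Xd[, 1]) + 4 * mad(Xd[, 1]))
  expect_lte(max(abs(clipped - median(Xd[, 1]))), 4 * mad(Xd[, 1]) + 1e-8)
})

test_that("band-pass attenuates a 0.2 Hz tone by at least 20 dB at TR 0.735 s", {
  set.seed(2)
  tr_s <- 0.735; nt <- 2000
  t <- (0:(nt - 1)) * tr_s
  x <- cbind(sin(2 * pi * 0.2 * t) + sin(2 * pi * 0.05 * t) + rnorm(nt, sd = 1e-3),
             rnorm(nt))
  y <- postprocess_timecourses(x, tr_s)
  pw <- function(v, f) {
    sp <- Mod(fft(v))^2
    fr <- (0:(nt - 1)) / (nt * tr_s)
    sum(sp[abs(fr - f) < 0.005])
  }
  atten_db <- 10 * log10((pw(y[, 1], 0.2) / pw(y[, 1], 0.05)) /
                           (pw(x[, 1], 0.2) / pw(x[, 1], 0.05)))
  expect_lt(atten_db, -20)
})

test_that("band edges outside (0, Nyquist) are rejected", {
  expect_error(postprocess_timecourses(matrix(rnorm(100), 50), 2,
                                       band = c(0.01, 0.3)), "Nyquist")
})

test_that("graphical lasso at vanishing penalty returns the input covariance", {
  set.seed(4)
  X <- matrix(rnorm(400 * 6), 400, 6)
  S <- cov(X)
  g <- graphical_lasso(S, 1e-8)
  expect_lt(max(abs(g$w - S)), 1e-4)
  expect_lt(max(abs(g$theta %*% g$w - diag(6))), 1e-4)
  g2 <- graphical_lasso(S, 0.1)
  expect_true(g2$converged)
  # penalty shrinks off-diagonals by at most lambda
  off <- abs(g2$w - S); diag(off) <- 0
  expect_lte(max(off), 0.1 + 1e-6)
})

test_that("windowed FNC at vanishing penalty matches tapered Pearson correlation", {
  set.seed(5)
  tc <- matrix(rnorm(200 * 8), 200, 8)
  tc[, 2] <- 0.6 * tc[, 1] + sqrt(1 - 0.36) * tc[, 2]
  taper <- make_taper(20, 3)
  wf_pen <- windowed_fnc(tc, taper, glasso_lambda = 1e-4)
  support <- length(taper)
  oracle <- t(vapply(wf_pen$starts, function(s)
    tapered_cor_z(tc[s:(s + support - 1), ], taper), numeric(n_fnc_pairs(8))))
  expect_lt(max(abs(wf_pen$z - oracle)), 0.02)
})

test_that("perfectly correlated ICNs saturate at the capped Fisher z", {
  set.seed(6)
  base <- rnorm(120)
  tc <- cbind(base, base, rnorm(120))
  wf <- windowed_fnc(tc, make_taper(20, 3), glasso_lambda = 0)
  expect_true(all(is.finite(wf$z)))
  expect_equal(max(wf$z[, 1]), atanh(1 - 1e-6))
})

test_that("independent white-noise ICNs give near-zero connectivity", {
  set.seed(7)
  tc <- matrix(rnorm(3000 * 4), 3000, 4)
  taper <- make_taper(60, 5)
  wf <- windowed_fnc(tc, taper, glasso_lambda = 0)
  expect_lt(mean(abs(wf$z)), 3 / sqrt(60))
  expect_lt(abs(mean(wf$z)), 0.05)
})

test_that("53 ICNs produce 1378-dimensional window vectors", {
  set.seed(8)
  tc <- matrix(rnorm(60 * 53), 60, 53)
  wf <- windowed_fnc(tc, make_taper(20, 3), glasso_lambda = 0)
  expect_equal(ncol(wf$z), 1378)
})
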