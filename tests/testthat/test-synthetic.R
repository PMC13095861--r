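test_that("design validation rejects impossible parameter combinations", {
  expect_error(synthetic_design(k_states = 1), "k_states")
  expect_error(synthetic_design(n_subjects = 4, n_components = 5), "n_components")
  expect_error(synthetic_design(maf_range = c(0, 0.5)), "maf_range")
  expect_error(synthetic_design(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(synthetic_design(effect_components = 9, n_components = 5),
               "effect_components")
})

test_that("generation is deterministic given the seed", {
  d <- tiny_design()
  t1 <- generate_ground_truth(d)
  t2 <- generate_ground_truth(d)
  expect_identical(t1$sources, t2$sources)
  expect_identical(t1$state_sequence, t2$state_sequence)
  expect_identical(generate_genotypes(d, t1)$dosage,
                   generate_genotypes(d, t2)$dosage)
  expect_identical(generate_timecourses(d, t1), generate_timecourses(d, t2))
})

test_that("planted source rows are super-Gaussian", {
  d <- synthetic_design(n_snps = 300, n_icns = 12, seed = 11)
  tr <- generate_ground_truth(d)
  expect_true(all(apply(tr$sources, 1, excess_kurtosis) > 0))
})

test_that("dosages are 0/1/2 with the designed minor allele frequencies", {
  d <- synthetic_design(n_subjects = 400, seed = 5)
  tr <- generate_ground_truth(d)
  g <- generate_genotypes(d, tr)
  expect_true(all(g$dosage %in% 0:2))
  emp <- colMeans(g$dosage) / 2
  expect_true(all(emp >= d$maf_range[1] - 0.02 & emp <= d$maf_range[2] + 0.02))
  expect_lt(max(abs(emp - g$maf)), 0.02)
})

test_that("null SNPs are consistent with Hardy-Weinberg proportions", {
  d <- synthetic_design(n_subjects = 400, seed = 5)
  tr <- generate_ground_truth(d)
  g <- generate_genotypes(d, tr)
  nulls <- which(!tr$snp_active)
  expect_gt(length(nulls), 10)
  pvals <- vapply(nulls, function(j) {
    x <- g$dosage[, j]
    pm <- mean(x) / 2
    e <- length(x) * c((1 - pm)^2, 2 * pm * (1 - pm), pm^2)
    o <- tabulate(x + 1, 3)
    stat <- sum((o - e)^2 / pmax(e, 1e-12))
    pchisq(stat, df = 1, lower.tail = FALSE)
  }, 0)
  expect_gte(mean(pvals > 0.01), 0.9)
})

test_that("planted loading-dosage coupling survives discretization at high SNR", {
  hits <- vapply(1:10, function(s) {
    d <- synthetic_design(n_subjects = 500, n_components = 1, snr = 100, seed = s)
    tr <- generate_ground_truth(d)
    g <- generate_genotypes(d, tr)
    w <- tr$sources[1, seq_len(d$n_snps)]
    top <- order(abs(w), decreasing = TRUE)[1:5]
    all(abs(vapply(top, function(j)
      cor(g$dosage[, j], tr$loadings[, 1] * w[j]), 0)) > 0.5)
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("an empty SNP panel yields an empty matrix with subject ids intact", {
  d <- synthetic_design(n_snps = 0)
  tr <- generate_ground_truth(d)
  g <- generate_genotypes(d, tr)
  expect_equal(dim(g$dosage), c(d$n_subjects, 0))
  expect_equal(rownames(g$dosage), tr$subject_ids)
})

test_that("windows of long-dwell time courses recover the planted state sequence", {
  d <- synthetic_design(n_subjects = 4, n_snps = 30, n_icns = 6,
                        n_timepoints = 600, k_states = 3, n_components = 2,
                        dwell_mean = 150, seed = 13)
  tr <- generate_ground_truth(d)
  tcs <- generate_timecourses(d, tr)
  taper <- make_taper()
  support <- length(taper)
  acc <- vapply(seq_along(tcs), function(i) {
    wf <- windowed_fnc(tcs[[i]], taper, glasso_lambda = 0)
    got <- assign_windows(list(centroids = fisher_z(tr$state_centroids)), wf)
    truth_lab <- vapply(wf$starts, function(s) {
      seg <- tr$state_sequence[[i]][s:(s + support - 1)]
      as.integer(names(which.max(table(seg))))
    }, 0L)
    mean(got == truth_lab)
  }, 0)
  expect_gt(mean(acc), 0.8)
})

test_that("a validation cohort generated from a template shares its population", {
  d1 <- tiny_design()
  t1 <- generate_ground_truth(d1)
  d2 <- synthetic_design(n_subjects = 200, n_snps = 60, n_icns = 6,
                         n_timepoints = 250, k_states = 3, n_components = 3,
                         effect_components = 2, effect_size = 0.5, seed = 99)
  t2 <- generate_ground_truth(d2, template = t1)
  expect_identical(t2$sources, t1$sources)
  expect_identical(t2$state_centroids, t1$state_centroids)
  expect_false(identical(t2$loadings[1:30, ], t1$loadings[1:30, ]))
  shift <- colMeans(t2$loadings[t2$diagnosis == 1, ]) -
    colMeans(t2$loadings[t2$diagnosis == 0, ])
  expect_gt(shift[2], 0.2)
  d_bad <- synthetic_design(n_subjects = 30, n_snps = 10, n_icns = 6,
                            k_states = 3, n_components = 3)
  expect_error(generate_ground_truth(d_bad, template = t1), "incompatible")
})

test_that("fixture bundles are complete, re-readable and checksum-stable", {
  d <- synthetic_design(n_subjects = 5, n_snps = 20, n_icns = 5,
                        n_timepoints = 60, k_states = 2, n_components = 2,
                        seed = 3)
  tr <- generate_ground_truth(d)
  out1 <- file.path(tempdir(), "bundle1")
  out2 <- file.path(tempdir(), "bundle2")
  m1 <- write_fixture_bundle(d, tr, out1)
  m2 <- write_fixture_bundle(d, tr, out2)
  expect_equal(nrow(m1), 5 + 6) # 5 time-course files + 6 tables/archives
  expect_identical(m1$md5[m1$file != "ground_truth.rds"],
                   m2$md5[m2$file != "ground_truth.rds"])
  b <- read_bundle(out1)
  expect_equal(dim(b$genotypes), c(5, 20))
  expect_equal(length(b$timecourses), 5)
  expect_equal(b$tr_seconds, d$tr_seconds)
  expect_equal(nrow(b$icn_legend), 5)
  unlink(c(out1, out2), recursive = TRUE)
})
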