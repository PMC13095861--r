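make_result_for_report <- function(s_snp, s_dfnc, state = 1L) {
  S <- rbind(c(s_snp, s_dfnc))
  colnames(S) <- c(paste0("rs", seq_along(s_snp)),
                   paste0("pair", seq_along(s_dfnc)))
  structure(list(S = S, C = 1L, p_snp = length(s_snp),
                 p_dfnc = length(s_dfnc), state = state,
                 feature_ids = colnames(S)),
            class = "fusion_result")
}

test_that("thresholding keeps exactly the planted outlier and is monotone", {
  set.seed(1)
  snp <- runif(500, -1, 1) # bounded nulls: |z| stays below 2 in-block
  snp[42] <- 30
  dfnc <- rnorm(n_fnc_pairs(6))
  res <- make_result_for_report(snp, dfnc)
  ts3 <- suppressWarnings(top_features(res, 1, 3))
  expect_equal(ts3$snps$snp, "rs42")
  ts5 <- suppressWarnings(top_features(res, 1, 5))
  expect_true(all(ts5$snps$snp %in% ts3$snps$snp))
  expect_true(all(ts5$pairs$pair %in% ts3$pairs$pair))
})

test_that("a constant source block yields no features, with a warning", {
  res <- make_result_for_report(rep(1, 100), rnorm(n_fnc_pairs(5)))
  expect_warning(ts <- top_features(res, 1, 3), "constant")
  expect_equal(nrow(ts$snps), 0)
})

test_that("the Gaussian tail predicts the retained count at threshold 3", {
  set.seed(2)
  res <- make_result_for_report(rnorm(1e4), rnorm(n_fnc_pairs(5)))
  ts <- suppressWarnings(top_features(res, 1, 3))
  expected <- 2 * pnorm(-3) * 1e4 # about 27
  expect_lt(abs(nrow(ts$snps) - expected), 4 * sqrt(expected))
})

test_that("overlap ratios follow the Jaccard definition", {
  expect_equal(overlap_ratio(c("a", "b"), c("a", "b")), 100)
  expect_equal(overlap_ratio(c("a", "b"), c("c", "d")), 0)
  expect_equal(overlap_ratio(c("a", "b", "c"), c("b", "c", "d", "e")), 40)
  expect_equal(overlap_ratio(c("a", "b", "c"), c("b", "c", "d", "e"),
                             method = "overlap"), 100 * 2 / 3)
  expect_true(is.na(overlap_ratio(character(0), character(0))))
})

test_that("domain summaries aggregate counts, signs and hubs correctly", {
  legend <- data.frame(index = 1:6, label = sprintf("ICN%02d", 1:6),
                       domain = c("SC", "SC", "CC", "CC", "DMN", "DMN"))
  pairs <- data.frame(pair = 1:4, i = c(1, 1, 1, 3), j = c(2, 3, 5, 4),
                      weight = c(0.5, -0.2, 0.3, 0.4))
  ds <- domain_summary(pairs, icn_legend = legend, hub_fraction = 0.5)
  expect_equal(sum(ds$counts$positive + ds$counts$negative), nrow(pairs))
  expect_equal(ds$hubs$icn, c(1L, 3L)) # ICNs in >= half the retained pairs
  within_sc <- ds$counts[ds$counts$domain_a == "SC" & ds$counts$domain_b == "SC", ]
  expect_equal(within_sc$positive, 1)
  pairs_bad <- data.frame(pair = 1, i = 1, j = 9, weight = 1)
  expect_error(domain_summary(pairs_bad, icn_legend = legend), "unlabeled")
})

test_that("report rendering is complete, bannered when empty, and byte-stable", {
  set.seed(3)
  legend <- data.frame(index = 1:5, label = sprintf("ICN%02d", 1:5),
                       domain = c("SC", "CC", "CC", "DMN", "CB"))
  snp <- rnorm(300); snp[7] <- 12
  dfnc <- rnorm(n_fnc_pairs(5)); dfnc[2] <- -10
  res <- make_result_for_report(snp, dfnc)
  ts <- top_features(res, 1, 3, icn_legend = legend,
                     snp_annotation = data.frame(snp = "rs7", chromosome = 2,
                                                 position = 100, gene = "G1"))
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  render_reports(d1, top_sets = list(ts), params = list(seed = 1))
  render_reports(d2, top_sets = list(ts), params = list(seed = 1))
  edges <- read.table(file.path(d1, "connectogram_edges.tsv"), header = TRUE)
  expect_equal(nrow(edges), nrow(ts$pairs))
  expect_identical(unname(tools::md5sum(file.path(d1, "connectogram_edges.tsv"))),
                   unname(tools::md5sum(file.path(d2, "connectogram_edges.tsv"))))
  d3 <- file.path(tempdir(), "rep3")
  render_reports(d3, top_sets = list())
  expect_true(any(grepl("0 components",
                        readLines(file.path(d3, "run_summary.tsv")))))
  unlink(c(d1, d2, d3), recursive = TRUE)
})
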