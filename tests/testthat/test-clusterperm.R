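test_that("cluster finder matches a brute-force oracle on random series", {
  set.seed(61)
  for (rep in 1:200) {
    v <- rnorm(60, sd = 1.5)
    thr <- runif(1, 0.5, 3)
    s <- stat_series(v, seq_along(v) - 1)
    cl <- find_clusters(s, threshold = thr)
    oracle <- brute_clusters(v, thr)
    expect_equal(nrow(cl), length(oracle))
    if (nrow(cl) > 0) {
      expect_equal(cl$start_idx, vapply(oracle, `[[`, 0, "start"),
                   ignore_attr = TRUE)
      expect_equal(cl$end_idx, vapply(oracle, `[[`, 0, "end"),
                   ignore_attr = TRUE)
      expect_equal(cl$mass, vapply(oracle, `[[`, 0, "mass"),
                   tolerance = 1e-12, ignore_attr = TRUE)
      expect_equal(cl$sign, vapply(oracle, `[[`, 0L, "sign"),
                   ignore_attr = TRUE)
    }
  }
})

test_that("cluster finder handles hand-built edge cases", {
  t <- 0:9
  cl <- function(v, thr = 1.96) find_clusters(stat_series(v, t), thr)
  # all sub-threshold
  expect_equal(nrow(cl(rep(1.9, 10))), 0)
  # exactly at threshold: strict inequality, no cluster
  expect_equal(nrow(cl(rep(1.96, 10))), 0)
  # single suprathreshold point is a length-1 cluster
  one <- rep(0, 10); one[4] <- 3
  res <- cl(one)
  expect_equal(res$start_idx, 4)
  expect_equal(res$end_idx, 4)
  expect_equal(res$mass, 3)
  # sign change splits clusters even when adjacent
  v <- c(3, 3, -3, -3, rep(0, 6))
  res <- cl(v)
  expect_equal(nrow(res), 2)
  expect_equal(res$sign, c(1, -1))
  expect_equal(res$mass, c(6, -6))
  # cluster running to the series edge is closed correctly
  v <- c(rep(0, 7), 4, 4, 4)
  res <- cl(v)
  expect_equal(res$end_idx, 10)
  expect_equal(res$mass, 12)
  # start/end times are reported in ms
  expect_equal(res$start_ms, 7)
  expect_equal(res$end_ms, 9)
})

test_that("max_cluster_mass agrees with the brute-force oracle", {
  set.seed(71)
  for (rep in 1:100) {
    v <- rnorm(40, sd = 1.4)
    expect_equal(max_cluster_mass(v, 1.96), brute_max_mass(v, 1.96),
                 tolerance = 1e-12)
  }
  expect_equal(max_cluster_mass(rep(0, 10), 1.96), 0)
})

test_that("pointwise statistics equal per-timepoint mixed-model t-values", {
  set.seed(81)
  d <- cb_design(n_subj = 5, n_item = 10)
  ep <- make_epochs(d, nt = 7, effect = 1, effect_idx = 3:5)
  x01 <- binary_indicator(d$prime_type, "prime_type")
  ps <- pointwise_stats(ep, d, window_ms = range(ep$time_ms))
  expect_equal(length(ps$values), 7)
  for (j in c(1, 4, 7)) {
    fit <- fit_lmm(ep$data[, j], cbind(prime_type = x01),
                   subject = d$subject_id, item = d$item_id)
    expect_equal(ps$values[j], unname(fit$t["prime_type"]), tolerance = 1e-5)
  }
  # effect timepoints show negative t (related coded 0, effect positive for
  # related trials, indicator codes unrelated)
  expect_lt(ps$values[4], -2)
})

test_that("score-mode permutation t equals an exact refit at the observed labels", {
  set.seed(91)
  d <- cb_design(n_subj = 5, n_item = 10)
  ep <- make_epochs(d, nt = 5, effect = 0.8, effect_idx = 2:4)
  rs <- permutation_test(ep, d, window_ms = range(ep$time_ms), n_perm = 30,
                         seed = 5, mode = "score")
  rr <- permutation_test(ep, d, window_ms = range(ep$time_ms), n_perm = 30,
                         seed = 5, mode = "refit")
  # observed series agree across modes up to optimizer tolerance
  expect_equal(rs$series$values, rr$series$values, tolerance = 1e-6)
  expect_equal(rs$max_abs_mass, rr$max_abs_mass, tolerance = 1e-5)
  # null draws use the same permutations; refit mode re-estimates variance
  # components per permutation, so require distribution-level agreement only
  expect_gt(cor(rs$null_distribution, rr$null_distribution), 0.9)
  expect_lt(abs(mean(rs$null_distribution) - mean(rr$null_distribution)),
            0.2 * (mean(rr$null_distribution) + 0.1))
})

test_that("permutation test is deterministic and respects the add-one rule", {
  set.seed(95)
  d <- cb_design(n_subj = 6, n_item = 12)
  ep <- make_epochs(d, nt = 21, effect = 1.2, effect_idx = 8:14)
  r1 <- permutation_test(ep, d, window_ms = range(ep$time_ms), n_perm = 200,
                         seed = 4)
  r2 <- permutation_test(ep, d, window_ms = range(ep$time_ms), n_perm = 200,
                         seed = 4)
  expect_identical(r1$clusters$mc_p, r2$clusters$mc_p)
  expect_identical(r1$null_distribution, r2$null_distribution)
  expect_equal(length(r1$null_distribution), 200)
  for (k in seq_len(nrow(r1$clusters))) {
    expect_equal(r1$clusters$mc_p[k],
                 (1 + sum(r1$null_distribution >=
                            abs(r1$clusters$mass[k]) - 1e-12)) / 201)
  }
  expect_gte(min(r1$clusters$mc_p), 1 / 201)
})

test_that("a strong injected effect is detected; a null series is not", {
  set.seed(99)
  d <- cb_design(n_subj = 8, n_item = 16)
  ep <- make_epochs(d, nt = 31, effect = 1.5, effect_idx = 10:20)
  res <- permutation_test(ep, d, window_ms = range(ep$time_ms), n_perm = 300,
                          seed = 7)
  expect_gt(nrow(res$clusters), 0)
  best <- which.max(abs(res$clusters$mass))
  expect_lt(res$clusters$mc_p[best], 0.05)
  # detected cluster overlaps the injected window (time 9..19 ms grid)
  expect_lt(res$clusters$start_ms[best], ep$time_ms[20])
  expect_gt(res$clusters$end_ms[best], ep$time_ms[10])
  # null data: min_p rarely small; no-cluster case gives p = 1
  ep0 <- make_epochs(d, nt = 11, effect = 0)
  res0 <- permutation_test(ep0, d, window_ms = range(ep0$time_ms),
                           n_perm = 200, seed = 8)
  if (nrow(res0$clusters) == 0) expect_equal(res0$min_p, 1)
  else expect_gt(res0$min_p, 0.01)
})

test_that("analysis window restricts which timepoints enter the test", {
  set.seed(103)
  d <- cb_design(n_subj = 6, n_item = 12)
  # effect entirely outside the analysis window
  ep <- make_epochs(d, nt = 31, effect = 2, effect_idx = 25:30)
  res <- permutation_test(ep, d, window_ms = c(ep$time_ms[1], ep$time_ms[15]),
                          n_perm = 100, seed = 9)
  expect_equal(length(res$series$values), 15)
  if (nrow(res$clusters) > 0)
    expect_true(all(res$clusters$end_ms <= ep$time_ms[15]))
  expect_error(permutation_test(ep, d, window_ms = c(-999, -900),
                                n_perm = 10, seed = 1),
               "window")
})

test_that("interaction variant returns sqrt-chi-squared series and valid p-values", {
  set.seed(107)
  d <- cb_design(n_subj = 6, n_item = 12)
  d$albright_score_o <- rnorm(nrow(d))
  ep <- make_epochs(d, nt = 9, effect = 0)
  # inject a label-by-score interaction at timepoints 4..6
  x01 <- binary_indicator(d$prime_type, "prime_type")
  for (j in 4:6)
    ep$data[, j] <- ep$data[, j] + 1.5 * x01 * d$albright_score_o
  res <- permutation_test(ep, d, window_ms = range(ep$time_ms), n_perm = 100,
                          seed = 11, interaction_with = "albright_score_o")
  expect_true(all(res$series$values >= 0))
  expect_equal(res$series$kind, "sqrt_chisq")
  expect_gt(max(res$series$values[4:6]), 1.96)
  if (nrow(res$clusters) > 0)
    expect_true(all(res$clusters$mc_p >= 1 / 101 & res$clusters$mc_p <= 1))
})

test_that("cluster test serializes to JSON", {
  set.seed(111)
  d <- cb_design(n_subj = 4, n_item = 8)
  ep <- make_epochs(d, nt = 9, effect = 1, effect_idx = 4:6)
  res <- permutation_test(ep, d, window_ms = range(ep$time_ms), n_perm = 50,
                          seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_cluster_test(res, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$n_perm, 50)
  expect_equal(obj$threshold, 1.96)
  if (nrow(res$clusters) > 0)
    expect_equal(obj$clusters$mass, res$clusters$mass, tolerance = 1e-10)
})
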