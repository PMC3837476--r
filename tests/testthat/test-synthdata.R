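test_that("design counterbalancing yields the expected trial counts", {
  spec <- simulation_spec(n_subjects = 16, trials_per_condition = 50, seed = 7)
  d <- generate_design(spec)
  expect_equal(nrow(d), 16 * 4 * 50)
  expect_equal(sum(d$prime_type == "related"), 1600)
  # per subject: 100 related + 100 unrelated word primes
  per_subj <- table(d$subject_id, d$prime_type)
  expect_true(all(per_subj == 100))
  # each (subject, item) pair occurs at most once
  expect_false(any(duplicated(d[, c("subject_id", "item_id")])))
  # within a version, each target takes exactly one prime type
  for (v in c("A", "B")) {
    sub <- d[d$version == v, ]
    expect_true(all(tapply(sub$prime_type, droplevels(sub$item_id),
                           function(x) length(unique(x))) == 1))
  }
  # minimal even design: one related + one unrelated per condition
  d2 <- generate_design(simulation_spec(n_subjects = 2,
                                        trials_per_condition = 2, seed = 1))
  counts <- table(d2$subject_id, d2$condition, d2$prime_type)
  expect_true(all(counts == 1))
  expect_error(generate_design(simulation_spec(trials_per_condition = 3)),
               "even")
})

test_that("nonword trials keep the 75/125 related/unrelated split in both versions", {
  spec <- simulation_spec(n_subjects = 4, trials_per_condition = 50,
                          include_nonwords = TRUE, seed = 2)
  d <- generate_design(spec)
  nw <- d[d$condition == "nonword", ]
  expect_equal(nrow(nw), 4 * 200)
  tab <- table(nw$subject_id, nw$prime_type)
  expect_true(all(tab[, "related"] == 75))
  expect_true(all(tab[, "unrelated"] == 125))
  # same items related in both versions
  rel_items <- tapply(nw$prime_type == "related", droplevels(nw$item_id),
                      function(x) length(unique(x)))
  expect_true(all(rel_items == 1))
})

test_that("reaction times follow the generative model exactly when noise-free", {
  spec <- simulation_spec(n_subjects = 4, trials_per_condition = 4,
                          priming_effects_ms = c(identity = 20, regular = 20,
                                                 irregular = 20,
                                                 pseudo_irregular = 20),
                          subject_sd = 0, item_sd = 0, residual_sd = 0,
                          seed = 11)
  d <- simulate_rts(generate_design(spec), spec)
  eff <- mean(d$rt_ms[d$prime_type == "unrelated"]) -
    mean(d$rt_ms[d$prime_type == "related"])
  expect_equal(eff, 20)
  expect_equal(unique(d$rt_ms[d$prime_type == "unrelated"]),
               spec$grand_mean_rt_ms)
})

test_that("simulation is deterministic under a fixed seed", {
  spec <- simulation_spec(n_subjects = 3, trials_per_condition = 4, seed = 42,
                          epoch_window_ms = c(-150, 250))
  d1 <- simulate_rts(generate_design(spec), spec)
  d2 <- simulate_rts(generate_design(spec), spec)
  expect_identical(d1, d2)
  e1 <- simulate_roi_timecourses(d1, spec)
  e2 <- simulate_roi_timecourses(d2, spec)
  expect_identical(e1$data, e2$data)
})

test_that("RT variance decomposes into its generative components", {
  spec <- simulation_spec(n_subjects = 50, trials_per_condition = 52,
                          subject_sd = 40, item_sd = 30, residual_sd = 80,
                          priming_effects_ms = c(identity = 0, regular = 0,
                                                 irregular = 0,
                                                 pseudo_irregular = 0),
                          seed = 5)
  d <- simulate_rts(generate_design(spec), spec)  # 10,400 trials
  total <- var(d$rt_ms)
  expect_lt(abs(total - (40^2 + 30^2 + 80^2)) / (40^2 + 30^2 + 80^2), 0.10)
  # fitted subject means recover the subject SD within 10% (shrinkage-free
  # check: SD of subject means vs sqrt(subject_sd^2 + (item+resid)/m))
  m <- tapply(d$rt_ms, d$subject_id, mean)
  n_per <- 4 * 52
  expected_sd <- sqrt(40^2 + (30^2 + 80^2) / n_per)
  expect_lt(abs(sd(m) - expected_sd) / expected_sd, 0.10)
})

test_that("noise-free epochs carry exactly the injected priming bump", {
  spec <- simulation_spec(n_subjects = 2, trials_per_condition = 2,
                          noise_sd = 0, epoch_window_ms = c(-150, 300),
                          effect_windows = list(
                            identity = list(start_ms = 158, end_ms = 208,
                                            amplitude = 1, direction = 1),
                            regular = list(start_ms = 158, end_ms = 208,
                                           amplitude = 1, direction = 1),
                            irregular = list(start_ms = 158, end_ms = 208,
                                             amplitude = 1, direction = 1),
                            pseudo_irregular = list(start_ms = 158,
                                                    end_ms = 208,
                                                    amplitude = 1,
                                                    direction = 1)),
                          seed = 3)
  d <- generate_design(spec)
  ep <- simulate_roi_timecourses(d, spec)
  diff <- colMeans(ep$data[d$prime_type == "related", ]) -
    colMeans(ep$data[d$prime_type == "unrelated", ])
  bump <- megpriming:::effect_bump(ep$time_ms, 158, 208, "gaussian")
  expect_equal(diff, bump, tolerance = 1e-12)
  # boxcar variant is exactly the indicator
  spec$effect_shape <- "boxcar"
  ep2 <- simulate_roi_timecourses(d, spec)
  diff2 <- colMeans(ep2$data[d$prime_type == "related", ]) -
    colMeans(ep2$data[d$prime_type == "unrelated", ])
  expect_equal(diff2, as.numeric(ep2$time_ms >= 158 & ep2$time_ms <= 208),
               tolerance = 1e-12)
})

test_that("score-scaled effects vanish for zero-score trials", {
  spec <- simulation_spec(n_subjects = 2, trials_per_condition = 4,
                          noise_sd = 0, scale_effect_by_albright = TRUE,
                          epoch_window_ms = c(-150, 300), seed = 9)
  d <- generate_design(spec)
  d$albright_score[d$condition == "irregular"] <-
    rep(c(0, 1), 4)[seq_len(sum(d$condition == "irregular"))]
  ep <- simulate_roi_timecourses(d, spec)
  rel_irr <- d$prime_type == "related" & d$condition == "irregular"
  zero_rows <- which(rel_irr & d$albright_score == 0)
  one_rows <- which(rel_irr & d$albright_score == 1)
  template <- megpriming:::evoked_template(ep$time_ms)
  for (r in zero_rows) expect_equal(ep$data[r, ], template, tolerance = 1e-12)
  for (r in one_rows) expect_gt(max(abs(ep$data[r, ] - template)), 0.1)
})

test_that("null generator: related-unrelated mean difference stays within 3 SE of zero", {
  spec <- simulation_spec(n_subjects = 8, trials_per_condition = 10,
                          epoch_window_ms = c(-50, 150),
                          effect_windows = list(
                            identity = list(start_ms = 0, end_ms = 50,
                                            amplitude = 0, direction = 1),
                            regular = list(start_ms = 0, end_ms = 50,
                                           amplitude = 0, direction = 1),
                            irregular = list(start_ms = 0, end_ms = 50,
                                             amplitude = 0, direction = 1),
                            pseudo_irregular = list(start_ms = 0, end_ms = 50,
                                                    amplitude = 0,
                                                    direction = 1)),
                          seed = 21)
  d <- generate_design(spec)
  rel <- d$prime_type == "related"
  # Monte-Carlo over seeds: pool differences across repetitions
  diffs <- sapply(1:8, function(s) {
    spec$seed <- 100 + s
    ep <- simulate_roi_timecourses(d, spec)
    colMeans(ep$data[rel, ]) - colMeans(ep$data[!rel, ])
  })
  se <- spec$noise_sd * sqrt(1 / sum(rel) + 1 / sum(!rel)) / sqrt(ncol(diffs))
  expect_true(all(abs(rowMeans(diffs)) < 3.5 * se))
})

test_that("irregular AlbrightScores match the target Beta moments and frequency coupling", {
  spec <- simulation_spec(n_subjects = 2, trials_per_condition = 400, seed = 17)
  d <- generate_design(spec)
  irr <- unique(d[d$condition == "irregular",
                  c("item_id", "albright_score", "log_surface_freq")])
  expect_true(all(irr$albright_score >= 0 & irr$albright_score <= 1))
  expect_lt(abs(mean(irr$albright_score) - 0.514), 0.04)
  expect_lt(abs(sd(irr$albright_score) - 0.228), 0.04)
  expect_lt(abs(cor(irr$albright_score, irr$log_surface_freq) - 0.29), 0.15)
  reg <- unique(d[d$condition == "regular", c("item_id", "albright_score")])
  expect_lt(abs(mean(reg$albright_score) - 0.975), 0.01)
})

test_that("source grid carries the effect only inside the patch", {
  spec <- simulation_spec(n_subjects = 2, trials_per_condition = 4,
                          noise_sd = 0, epoch_window_ms = c(-150, 300),
                          seed = 31)
  d <- generate_design(spec)
  src <- simulate_source_grid(d, spec, patch = 17, n_sources = 24)
  rel <- d$prime_type == "related"
  for (s in c(1, 10, 17, 24)) {
    diff <- colMeans(src$data[!rel, s, ]) - colMeans(src$data[rel, s, ])
    if (s == 17) expect_gt(max(abs(diff)), 0.1)
    else expect_lt(max(abs(diff)), 1e-12)
  }
  # mask labelling covers the grid and patch validation works
  expect_equal(length(src$source_labels), 24)
  expect_error(simulate_source_grid(d, spec, patch = 99, n_sources = 24),
               "outside")
  expect_error(simulate_source_grid(d, spec, patch = 1, n_sources = 0),
               "nonempty")
})

test_that("simulation spec round-trips through JSON", {
  spec <- simulation_spec(n_subjects = 5, trials_per_condition = 8, seed = 77,
                          noise_sd = 2.5)
  path <- withr::local_tempfile(fileext = ".json")
  write_simulation_spec(spec, path)
  spec2 <- read_simulation_spec(path)
  expect_equal(spec2, spec)
})
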