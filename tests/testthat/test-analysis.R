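fast_config <- function(n_perm = 100, seed = 1L, ...) {
  analysis_config(n_perm = n_perm, seed = seed, ...)
}

test_that("analysis config round-trips through YAML", {
  cfg <- fast_config(n_perm = 123, seed = 9L, late_window_ms = c(250, 450))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_analysis_config(cfg, path)
  cfg2 <- read_analysis_config(path)
  expect_equal(cfg2, cfg)
  expect_error(analysis_config(threshold = -1))
  expect_error(analysis_config(n_perm = 0))
})

test_that("behavioral analysis recovers injected priming effects per condition", {
  spec <- simulation_spec(n_subjects = 8, trials_per_condition = 16,
                          priming_effects_ms = c(identity = 60, regular = 40,
                                                 irregular = 20,
                                                 pseudo_irregular = 20),
                          subject_sd = 20, item_sd = 10, residual_sd = 25,
                          seed = 41)
  tr <- simulate_rts(generate_design(spec), spec)
  rep <- run_behavioral(tr, fast_config(n_perm = 200, seed = 2L))
  expect_s3_class(rep, "priming_report")
  expect_setequal(names(rep$conditions), WORD_CONDITIONS)
  eff <- sapply(rep$conditions, `[[`, "priming_ms")
  expect_lt(max(abs(eff - c(60, 40, 20, 20) *
                      (names(eff) %in% names(eff)))), 15)
  expect_gt(eff["identity"], eff["irregular"])
  # all injected effects large enough to reject
  expect_true(all(sapply(rep$conditions, `[[`, "mc_p") < 0.05))
  # positive priming must come with negative indicator t (unrelated coded 1
  # would flip it; here the indicator codes unrelated, so t is positive)
  expect_true(all(sapply(rep$conditions, `[[`, "t") > 0))
  # equal irregular/pseudo effects: interaction present but small
  expect_false(is.null(rep$prime_by_pseudo_irregularity))
  expect_gte(rep$prime_by_pseudo_irregularity$chi_sq, 0)
  expect_gt(rep$prime_by_pseudo_irregularity$p, 0.001)
})

test_that("behavioral analysis skips under-filled conditions with a warning", {
  spec <- simulation_spec(n_subjects = 2, trials_per_condition = 2, seed = 43)
  tr <- simulate_rts(generate_design(spec), spec)
  tr <- tr[!(tr$condition == "identity" & tr$prime_type == "related"), ]
  expect_warning(rep <- run_behavioral(tr, fast_config(n_perm = 20)),
                 "identity")
  expect_false("identity" %in% names(rep$conditions))
})

test_that("anatomical M170 analysis detects the evoked peak and the priming cluster", {
  spec <- simulation_spec(n_subjects = 6, trials_per_condition = 6,
                          noise_sd = 0.4, epoch_window_ms = c(-150, 300),
                          seed = 47)
  d <- generate_design(spec)
  ep <- simulate_roi_timecourses(d, spec)
  rep <- run_meg_analysis(ep, d, "anatomical_m170",
                          fast_config(n_perm = 150, seed = 3L))
  expect_equal(rep$window_provenance, "detected_peak")
  # evoked template peaks at 170 ms
  expect_lt(abs(rep$peak_ms - 170), 15)
  expect_equal(diff(rep$window_ms), 50)
  expect_gt(nrow(rep$test$clusters), 0)
  expect_lt(rep$test$min_p, 0.05)
})

test_that("M100 analysis uses the fixed early window and stays null without an effect", {
  spec <- simulation_spec(n_subjects = 6, trials_per_condition = 6,
                          epoch_window_ms = c(-150, 300), seed = 53)
  d <- generate_design(spec)
  ep <- simulate_roi_timecourses(d, spec)  # effects live at 158-208 only
  rep <- run_meg_analysis(ep, d, "m100",
                          fast_config(n_perm = 150, seed = 5L),
                          conditions = c("identity", "regular"))
  expect_equal(rep$window_ms, c(75, 125))
  expect_equal(rep$window_provenance, "fixed_center_100")
  expect_gt(rep$test$min_p, 0.01)
})

test_that("late-window analysis reports per-condition tests and the interaction", {
  spec <- simulation_spec(n_subjects = 5, trials_per_condition = 4,
                          epoch_window_ms = c(-150, 500), seed = 59)
  d <- generate_design(spec)
  ep <- simulate_roi_timecourses(d, spec)
  rep <- run_meg_analysis(ep, d, "late", fast_config(n_perm = 60, seed = 7L))
  expect_equal(rep$window_ms, c(300, 500))
  expect_setequal(names(rep$per_condition), WORD_CONDITIONS)
  expect_false(is.null(rep$prime_by_pseudo_irregularity))
  expect_equal(rep$prime_by_pseudo_irregularity$kind, "sqrt_chisq")
  # dropping pseudo-irregular removes the interaction stage
  rep2 <- run_meg_analysis(ep, d, "late", fast_config(n_perm = 40, seed = 7L),
                           conditions = c("identity", "regular", "irregular"))
  expect_null(rep2$prime_by_pseudo_irregularity)
  expect_error(run_meg_analysis(ep, d, "late", fast_config(n_perm = 10),
                                conditions = "nonexistent"),
               "missing")
})

test_that("fROI analysis localizes inside the simulated patch and tests both conditions", {
  spec <- simulation_spec(n_subjects = 3, trials_per_condition = 6,
                          noise_sd = 0.3, epoch_window_ms = c(-150, 300),
                          seed = 61)
  d <- generate_design(spec)
  src <- simulate_source_grid(d, spec, patch = 2:4, n_sources = 16)
  rep <- run_meg_analysis(src, d, "froi", fast_config(n_perm = 100, seed = 9L))
  expect_equal(rep$analysis, "froi")
  expect_true(all(rep$froi$sources %in% 2:4))
  # the priming-difference peak sits in the injected 158-208 window
  expect_gt(rep$peak_ms, 140)
  expect_lt(rep$peak_ms, 230)
  expect_setequal(names(rep$per_condition),
                  c("irregular", "pseudo_irregular"))
  for (s in rep$per_condition) {
    expect_gte(s$min_p, 1 / (s$n_perm + 1))
    expect_lte(s$min_p, 1)
  }
  expect_s3_class(rep$froi_epochs, "epoch_set")
})

test_that("albright analysis runs the interaction and the score-bin tests", {
  spec <- simulation_spec(n_subjects = 4, trials_per_condition = 10,
                          noise_sd = 0.5, epoch_window_ms = c(-150, 300),
                          scale_effect_by_albright = TRUE, seed = 67)
  d <- generate_design(spec)
  ep <- simulate_roi_timecourses(d, spec)
  rep <- run_albright_analysis(ep, d, fast_config(n_perm = 80, seed = 11L),
                               window_ms = c(158, 208))
  expect_equal(rep$analysis, "albright")
  expect_equal(rep$interaction$kind, "sqrt_chisq")
  expect_gte(rep$interaction$min_p, 1 / 81)
  expect_true(all(c("high", "low") %in% names(rep$by_bin)))
  for (s in rep$by_bin) {
    expect_equal(s$kind, "t")
    expect_gte(s$min_p, 1 / 81)
    expect_lte(s$min_p, 1)
  }
})

test_that("reports are deterministic and serialize byte-identically", {
  spec <- simulation_spec(n_subjects = 4, trials_per_condition = 4,
                          epoch_window_ms = c(-150, 300), seed = 71)
  d <- generate_design(spec)
  ep <- simulate_roi_timecourses(d, spec)
  cfg <- fast_config(n_perm = 50, seed = 13L)
  r1 <- run_meg_analysis(ep, d, "anatomical_m170", cfg)
  r2 <- run_meg_analysis(ep, d, "anatomical_m170", cfg)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_report(r1, p1)
  write_report(r2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  # text rendering mentions the analysis and window
  txt <- format_report(r1)
  expect_true(any(grepl("anatomical_m170", txt)))
  expect_true(any(grepl("window", txt)))
})
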