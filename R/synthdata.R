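# Synthetic masked-priming data: trial design, reaction times, and
# dSPM-like ROI / source-grid time courses with known generative structure.

WORD_CONDITIONS <- c("identity", "regular", "irregular", "pseudo_irregular")

# Per-condition covariate moments for targets/primes (letters; log wordform
# frequency). Irregular/regular frequency moments are those of the past-tense
# primes, which is the covariate entering the orthogonalization analysis.
COVARIATE_MOMENTS <- list(
  identity         = list(len = c(5.68, 1.04), freq = c(2.60, 0.51)),
  regular          = list(len = c(4.14, 0.45), freq = c(2.88, 0.50)),
  irregular        = list(len = c(4.20, 0.76), freq = c(2.76, 0.68)),
  pseudo_irregular = list(len = c(3.88, 0.66), freq = c(2.50, 1.00)),
  nonword          = list(len = c(4.48, 1.03), freq = c(2.54, 0.68))
)

#' Simulation specification for a masked-priming study
#'
#' Bundles every generative parameter of the synthetic experiment: design
#' size, reaction-time model, evoked-response model, and noise model. The
#' defaults emulate a 16-subject masked-priming lexical decision study with
#' four word conditions of 50 trials each, RT priming effects of
#' 33.3 / 22.5 / 14.2 / 14.6 ms (identity / regular / irregular /
#' pseudo-irregular), a grand mean RT of 620.7 ms with a total SD near
#' 178.7 ms, and 1000 Hz source-estimate epochs spanning (-150, +500) ms
#' around target onset.
#'
#' The RT variance is decomposed as subject_sd = 125, item_sd = 80,
#' residual_sd = 100 ms: the residual scale is anchored so that the implied
#' standard error of a condition's priming contrast at 800 trials
#' (2 * residual_sd / sqrt(800) ~ 7.1 ms) reproduces the t-values such
#' effects typically show at this scale, and the three components sum to the
#' stated total SD.
#'
#' @param n_subjects number of subjects (default 16).
#' @param trials_per_condition word-target trials per condition per subject
#'   (default 50); must be even so related/unrelated split evenly.
#' @param priming_effects_ms named numeric map condition -> facilitation in ms
#'   (subtracted from related-prime RTs).
#' @param grand_mean_rt_ms grand mean reaction time.
#' @param subject_sd,item_sd,residual_sd RT random-intercept and residual SDs (ms).
#' @param accuracy_rate Bernoulli success probability for simulated accuracy.
#' @param include_nonwords add a nonword condition (75/125 related/unrelated
#'   split, identical across versions), used only to exercise filters.
#' @param effect_windows named list condition -> list(start_ms, end_ms,
#'   amplitude, direction) describing the evoked priming effect injected for
#'   related-prime trials; direction +1 makes related trials more positive.
#' @param noise_sd marginal SD of the trial-level epoch noise (dSPM-like units).
#' @param ar1_rho lag-1 autocorrelation of the epoch noise at the sampling
#'   rate (default 0.95 at 1 kHz, giving realistically smooth trial noise).
#' @param effect_shape `"gaussian"` (SD = window width / 4, so ~95% of the
#'   bump's mass lies inside the window) or `"boxcar"`.
#' @param scale_effect_by_albright multiply the injected effect by the item's
#'   AlbrightScore (0 where undefined), creating a built-in score x prime-type
#'   interaction.
#' @param sampling_rate_hz epoch sampling rate (default 1000).
#' @param epoch_window_ms epoch limits relative to target onset.
#' @param seed integer seed governing all randomness.
#' @return an object of class `simulation_spec` (a validated list).
#' @export
simulation_spec <- function(n_subjects = 16,
                            trials_per_condition = 50,
                            priming_effects_ms = c(identity = 33.3,
                                                   regular = 22.5,
                                                   irregular = 14.2,
                                                   pseudo_irregular = 14.6),
                            grand_mean_rt_ms = 620.7,
                            subject_sd = 125,
                            item_sd = 80,
                            residual_sd = 100,
                            accuracy_rate = 0.944,
                            include_nonwords = FALSE,
                            effect_windows = list(
                              identity = list(start_ms = 158, end_ms = 208,
                                              amplitude = 1.0, direction = 1),
                              regular = list(start_ms = 158, end_ms = 208,
                                             amplitude = 0.7, direction = 1),
                              irregular = list(start_ms = 158, end_ms = 208,
                                               amplitude = 0.45, direction = 1),
                              pseudo_irregular = list(start_ms = 158, end_ms = 208,
                                                      amplitude = 0.45,
                                                      direction = 1)),
                            noise_sd = 1,
                            ar1_rho = 0.95,
                            effect_shape = c("gaussian", "boxcar"),
                            scale_effect_by_albright = FALSE,
                            sampling_rate_hz = 1000,
                            epoch_window_ms = c(-150, 500),
                            seed = 1L) {
  effect_shape <- match.arg(effect_shape)
  stopifnot(n_subjects >= 1, trials_per_condition >= 1,
            subject_sd >= 0, item_sd >= 0, residual_sd >= 0,
            noise_sd >= 0, ar1_rho >= 0, ar1_rho < 1,
            sampling_rate_hz > 0, length(epoch_window_ms) == 2,
            epoch_window_ms[1] < epoch_window_ms[2])
  for (nm in names(effect_windows)) {
    w <- effect_windows[[nm]]
    if (w$start_ms < epoch_window_ms[1] || w$end_ms > epoch_window_ms[2])
      stop(sprintf("effect window for '%s' lies outside the epoch window", nm))
    if (w$start_ms >= w$end_ms)
      stop(sprintf("effect window for '%s' is empty", nm))
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 trials_per_condition = as.integer(trials_per_condition),
                 priming_effects_ms = priming_effects_ms,
                 grand_mean_rt_ms = grand_mean_rt_ms,
                 subject_sd = subject_sd, item_sd = item_sd,
                 residual_sd = residual_sd, accuracy_rate = accuracy_rate,
                 include_nonwords = isTRUE(include_nonwords),
                 effect_windows = effect_windows,
                 noise_sd = noise_sd, ar1_rho = ar1_rho,
                 effect_shape = effect_shape,
                 scale_effect_by_albright = isTRUE(scale_effect_by_albright),
                 sampling_rate_hz = sampling_rate_hz,
                 epoch_window_ms = as.numeric(epoch_window_ms),
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf("<simulation_spec> %d subjects x %d trials/condition, seed %d\n",
              x$n_subjects, x$trials_per_condition, x$seed))
  invisible(x)
}

#' Round-trip a simulation spec through JSON
#' @param spec a `simulation_spec`.
#' @param path file path.
#' @export
write_simulation_spec <- function(spec, path) {
  x <- unclass(spec)
  x$priming_effects_ms <- as.list(x$priming_effects_ms)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_simulation_spec
#' @export
read_simulation_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$priming_effects_ms <- unlist(x$priming_effects_ms)
  x$effect_windows <- lapply(x$effect_windows, as.list)
  do.call(simulation_spec, x)
}

# Evaluate an expression under a temporary RNG seed, restoring prior state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate the counterbalanced trial design
#'
#' Builds the item pool (one shared pool per condition across subjects, so
#' each subject sees each word target exactly once) and the two-version
#' counterbalancing: within a version, half of each condition's targets take
#' a related prime and half an unrelated prime; the assignment flips between
#' versions A and B, and subjects alternate versions. Item covariates
#' (word length, log surface frequency, AlbrightScore for regular/irregular
#' items) are drawn once per item; related and unrelated presentations of an
#' item share its covariates, emulating pairwise length matching.
#'
#' AlbrightScore for irregular items is Beta-distributed with mean 0.514 and
#' SD 0.228, coupled to log surface frequency through a Gaussian copula
#' (latent correlation 0.29); regular items draw from a Beta with mean 0.975
#' and SD 0.025.
#'
#' @param spec a [simulation_spec()].
#' @return a trial-table `data.frame`: `subject_id`, `item_id`, `condition`,
#'   `prime_type`, `version`, `word_length`, `log_surface_freq`,
#'   `albright_score` (NA outside regular/irregular).
#' @export
generate_design <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (spec$trials_per_condition %% 2 != 0)
    stop("trials_per_condition must be even: related/unrelated cannot be split")
  with_seed(spec$seed, {
    items <- do.call(rbind, lapply(WORD_CONDITIONS, function(cond) {
      k <- spec$trials_per_condition
      m <- COVARIATE_MOMENTS[[cond]]
      df <- data.frame(
        item_id = sprintf("%s_%03d", abbreviate_condition(cond), seq_len(k)),
        condition = cond,
        word_length = pmax(2L, round(stats::rnorm(k, m$len[1], m$len[2]))),
        log_surface_freq = stats::rnorm(k, m$freq[1], m$freq[2]),
        albright_score = NA_real_,
        related_in_A = rep(c(TRUE, FALSE), k / 2),
        stringsAsFactors = FALSE)
      if (cond == "irregular") {
        cop <- albright_freq_copula(k, mean_score = 0.514, sd_score = 0.228,
                                    freq_mean = m$freq[1], freq_sd = m$freq[2],
                                    rho = 0.29)
        df$albright_score <- cop$score
        df$log_surface_freq <- cop$freq
      } else if (cond == "regular") {
        ab <- beta_moments(0.975, 0.025)
        df$albright_score <- stats::rbeta(k, ab[1], ab[2])
      }
      df
    }))
    if (spec$include_nonwords) {
      k <- 4L * spec$trials_per_condition
      m <- COVARIATE_MOMENTS$nonword
      n_rel <- round(k * 75 / 200)
      items <- rbind(items, data.frame(
        item_id = sprintf("nw_%03d", seq_len(k)),
        condition = "nonword",
        word_length = pmax(2L, round(stats::rnorm(k, m$len[1], m$len[2]))),
        log_surface_freq = stats::rnorm(k, m$freq[1], m$freq[2]),
        albright_score = NA_real_,
        related_in_A = rep(c(TRUE, FALSE), c(n_rel, k - n_rel)),
        stringsAsFactors = FALSE))
    }
    subjects <- data.frame(
      subject_id = sprintf("S%02d", seq_len(spec$n_subjects)),
      version = rep(c("A", "B"), length.out = spec$n_subjects),
      stringsAsFactors = FALSE)
    design <- merge(subjects, items, by = NULL)
    nonword <- design$condition == "nonword"
    # nonword prime assignment is identical in both versions
    design$prime_type <- ifelse(
      nonword,
      ifelse(design$related_in_A, "related", "unrelated"),
      ifelse((design$version == "A") == design$related_in_A,
             "related", "unrelated"))
    design$related_in_A <- NULL
    design <- design[order(design$subject_id, design$condition, design$item_id), ]
    rownames(design) <- NULL
    design$subject_id <- factor(design$subject_id)
    design$item_id <- factor(design$item_id)
    design
  })
}

abbreviate_condition <- function(cond) {
  c(identity = "id", regular = "reg", irregular = "irr",
    pseudo_irregular = "psi", nonword = "nw")[cond]
}

beta_moments <- function(mean, sd) {
  nu <- mean * (1 - mean) / sd^2 - 1
  if (nu <= 0) stop("infeasible Beta moments")
  c(mean * nu, (1 - mean) * nu)
}

albright_freq_copula <- function(k, mean_score, sd_score, freq_mean, freq_sd,
                                 rho) {
  z1 <- stats::rnorm(k)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(k)
  ab <- beta_moments(mean_score, sd_score)
  list(score = stats::qbeta(stats::pnorm(z1), ab[1], ab[2]),
       freq = freq_mean + freq_sd * z2)
}

#' Simulate reaction times and accuracy onto a design
#'
#' `rt = grand_mean + subject intercept + item intercept
#'  - priming_effect * 1[related] + residual`, with Normal random intercepts
#' of SD `subject_sd` / `item_sd` and Normal residuals of SD `residual_sd`.
#' Conditions absent from `priming_effects_ms` (e.g. nonwords) receive no
#' priming effect. Accuracy is Bernoulli(`accuracy_rate`), independent of RT.
#' Deterministic given `spec$seed`.
#'
#' @param design trial table from [generate_design()].
#' @param spec a [simulation_spec()].
#' @return the design with `rt_ms` and `accuracy` columns added.
#' @export
simulate_rts <- function(design, spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  if ("rt_ms" %in% names(design)) stop("design already carries rt_ms")
  with_seed(spec$seed + 1L, {
    subj <- levels(design$subject_id)
    item <- levels(design$item_id)
    s_int <- stats::setNames(stats::rnorm(length(subj), 0, spec$subject_sd), subj)
    i_int <- stats::setNames(stats::rnorm(length(item), 0, spec$item_sd), item)
    eff <- spec$priming_effects_ms[design$condition]
    eff[is.na(eff)] <- 0
    rt <- spec$grand_mean_rt_ms +
      s_int[as.character(design$subject_id)] +
      i_int[as.character(design$item_id)] -
      unname(eff) * (design$prime_type == "related") +
      stats::rnorm(nrow(design), 0, spec$residual_sd)
    design$rt_ms <- pmax(rt, 1)
    design$accuracy <- stats::rbinom(nrow(design), 1, spec$accuracy_rate)
    design
  })
}

# Smooth evoked template on the epoch grid: an M170-like positive deflection
# followed by a slower late negativity, in arbitrary dSPM-like units.
evoked_template <- function(time_ms) {
  2.0 * exp(-((time_ms - 170)^2) / (2 * 30^2)) -
    0.8 * exp(-((time_ms - 400)^2) / (2 * 80^2))
}

effect_bump <- function(time_ms, start_ms, end_ms, shape) {
  if (shape == "boxcar")
    return(as.numeric(time_ms >= start_ms & time_ms <= end_ms))
  mid <- (start_ms + end_ms) / 2
  sd <- (end_ms - start_ms) / 4
  exp(-((time_ms - mid)^2) / (2 * sd^2))
}

# AR(1)-colored Gaussian noise, marginal SD `sd`, lag-1 correlation `rho`;
# rows are trials. Stationary initialization.
ar1_noise <- function(n_trials, n_time, sd, rho) {
  if (sd <= 0) return(matrix(0, n_trials, n_time))
  e <- matrix(stats::rnorm(n_time * n_trials, 0, sd * sqrt(1 - rho^2)),
              n_time, n_trials)
  e[1, ] <- stats::rnorm(n_trials, 0, sd)
  x <- stats::filter(e, rho, method = "recursive")
  t(matrix(as.numeric(x), n_time, n_trials))
}

#' Simulate single-trial ROI time courses
#'
#' Each trial's series is a shared smooth evoked template plus, for
#' related-prime trials of conditions with an entry in
#' `spec$effect_windows`, a condition-specific effect bump
#' (`direction * amplitude * shape(t)`), plus AR(1)-colored Gaussian noise.
#' The related-minus-unrelated mean series therefore equals the injected bump
#' in expectation. With `scale_effect_by_albright`, the bump is multiplied by
#' the item's AlbrightScore (treated as 0 where undefined).
#'
#' @param design trial table (any stage; only design columns are used).
#' @param spec a [simulation_spec()].
#' @return an [epoch_set()] aligned to the rows of `design`.
#' @export
simulate_roi_timecourses <- function(design, spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  missing_w <- setdiff(intersect(unique(design$condition), WORD_CONDITIONS),
                       names(spec$effect_windows))
  if (length(missing_w))
    stop("no effect window defined for condition(s): ",
         paste(missing_w, collapse = ", "))
  time_ms <- seq(spec$epoch_window_ms[1], spec$epoch_window_ms[2],
                 by = 1000 / spec$sampling_rate_hz)
  with_seed(spec$seed + 2L, {
    n <- nrow(design)
    data <- matrix(rep(evoked_template(time_ms), each = n), n, length(time_ms))
    data <- data + effect_matrix(design, spec, time_ms)
    data <- data + ar1_noise(n, length(time_ms), spec$noise_sd, spec$ar1_rho)
    epoch_set(data, time_ms, trial_index = seq_len(n),
              sampling_rate_hz = spec$sampling_rate_hz, units = "dspm")
  })
}

# n x T matrix of injected effects (zero for unrelated trials).
effect_matrix <- function(design, spec, time_ms) {
  n <- nrow(design)
  out <- matrix(0, n, length(time_ms))
  rel <- design$prime_type == "related"
  for (cond in intersect(names(spec$effect_windows), unique(design$condition))) {
    w <- spec$effect_windows[[cond]]
    bump <- w$direction * w$amplitude *
      effect_bump(time_ms, w$start_ms, w$end_ms, spec$effect_shape)
    rows <- which(rel & design$condition == cond)
    if (!length(rows)) next
    gain <- rep(1, length(rows))
    if (spec$scale_effect_by_albright) {
      gain <- design$albright_score[rows]
      gain[is.na(gain)] <- 0
    }
    out[rows, ] <- out[rows, ] + outer(gain, bump)
  }
  out
}

#' Simulate a source-grid epoch set with a localized priming effect
#'
#' All sources share the evoked template (with a per-source sign emulating
#' free-orientation signed estimates); only sources inside `patch` carry the
#' condition-specific priming effect, injected facilitatorily: related-prime
#' trials are pulled toward zero relative to unrelated ones, so the
#' unrelated-minus-related difference at a patch source has the sign of that
#' source's evoked response.
#'
#' @param design trial table.
#' @param spec a [simulation_spec()].
#' @param patch integer source indices carrying the effect.
#' @param n_sources total number of sources on the grid.
#' @param source_labels anatomical mask label per source; default splits the
#'   grid into fusiform / inferior_temporal / middle_temporal / other blocks.
#' @param source_signs +1/-1 per source (default all +1).
#' @return a [source_epoch_set()].
#' @export
simulate_source_grid <- function(design, spec, patch, n_sources = 40,
                                 source_labels = NULL, source_signs = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (n_sources < 1) stop("source set must be nonempty")
  patch <- as.integer(patch)
  if (length(patch) && (min(patch) < 1 || max(patch) > n_sources))
    stop("patch indices outside the source set")
  if (is.null(source_labels)) {
    block <- ceiling(n_sources / 4)
    source_labels <- rep(c("fusiform", "inferior_temporal", "middle_temporal",
                           "other"), each = block)[seq_len(n_sources)]
  }
  stopifnot(length(source_labels) == n_sources)
  if (is.null(source_signs)) source_signs <- rep(1, n_sources)
  stopifnot(length(source_signs) == n_sources, all(abs(source_signs) == 1))
  time_ms <- seq(spec$epoch_window_ms[1], spec$epoch_window_ms[2],
                 by = 1000 / spec$sampling_rate_hz)
  n <- nrow(design)
  nt <- length(time_ms)
  eff <- effect_matrix(design, spec, time_ms)  # facilitatory magnitude
  template <- evoked_template(time_ms)
  with_seed(spec$seed + 3L, {
    data <- array(0, dim = c(n, n_sources, nt))
    for (s in seq_len(n_sources)) {
      x <- matrix(rep(source_signs[s] * template, each = n), n, nt)
      if (s %in% patch) x <- x - source_signs[s] * eff
      data[, s, ] <- x + ar1_noise(n, nt, spec$noise_sd, spec$ar1_rho)
    }
    source_epoch_set(data, source_labels, time_ms, trial_index = seq_len(n),
                     sampling_rate_hz = spec$sampling_rate_hz, units = "dspm")
  })
}
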