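# End-to-end orchestration of the behavioral and MEG analyses: behavioral RT
# priming per condition, anatomical-ROI M100/M170 windows, the late
# (M350/N400m) window, fROI localization and testing, and the AlbrightScore
# interaction.

#' Analysis configuration
#'
#' Window rules and test parameters shared by the orchestrated analyses:
#' the M100 window is 50 ms centered at 100 ms; the M170 window is 50 ms
#' centered at a detected peak (searched in `peak_search_ms`); the late
#' window is the fixed 300-500 ms interval. Cluster-forming threshold 1.96
#' (|t| > 1.96, or sqrt(chi^2) > 1.96 for interactions) and 10,000
#' permutations by default (reducible for speed).
#'
#' @param threshold cluster-forming threshold.
#' @param n_perm permutations per test.
#' @param seed integer seed for all randomized steps.
#' @param peak_search_ms search window for the M170 peak.
#' @param m100_center_ms center of the M100 window.
#' @param window_width_ms width of peak-centered windows.
#' @param late_window_ms fixed late analysis window.
#' @param baseline_ms baseline-correction interval.
#' @param lowpass_hz low-pass cutoff.
#' @param perm_scheme permutation scheme (see [permutation_test()]).
#' @param froi_conditions localizer conditions for the fROI.
#' @param froi_masks permitted anatomical masks for the fROI.
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(threshold = 1.96, n_perm = 10000, seed = 1L,
                            peak_search_ms = c(100, 250),
                            m100_center_ms = 100, window_width_ms = 50,
                            late_window_ms = c(300, 500),
                            baseline_ms = c(-150, -50), lowpass_hz = 40,
                            perm_scheme = "within_subject",
                            froi_conditions = c("identity", "regular"),
                            froi_masks = c("fusiform", "inferior_temporal")) {
  stopifnot(threshold > 0, n_perm >= 1)
  structure(list(threshold = threshold, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), peak_search_ms = peak_search_ms,
                 m100_center_ms = m100_center_ms,
                 window_width_ms = window_width_ms,
                 late_window_ms = late_window_ms, baseline_ms = baseline_ms,
                 lowpass_hz = lowpass_hz, perm_scheme = perm_scheme,
                 froi_conditions = froi_conditions, froi_masks = froi_masks),
            class = "analysis_config")
}

#' Round-trip an analysis config through YAML
#' @param config an [analysis_config()].
#' @param path file path.
#' @export
write_analysis_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_analysis_config
#' @export
read_analysis_config <- function(path) {
  do.call(analysis_config, yaml::read_yaml(path))
}

subset_epochs <- function(epochs, rows) {
  epoch_set(epochs$data[rows, , drop = FALSE], epochs$time_ms,
            trial_index = epochs$trial_index[rows],
            sampling_rate_hz = epochs$sampling_rate_hz, units = epochs$units)
}

#' Behavioral RT priming analysis
#'
#' Per word condition: the marginal priming effect in ms (mean unrelated
#' minus mean related RT), the crossed random-intercept LMM t-value for
#' prime type, and the Monte-Carlo permutation p-value; plus the
#' PrimeType x Pseudo-irregularity interaction, tested by likelihood-ratio
#' comparison of nested ML fits on the irregular + pseudo-irregular trials
#' only. Trials are expected to have passed subject exclusion and RT
#' trimming already.
#'
#' @param trials preprocessed trial table.
#' @param config an [analysis_config()].
#' @return a list of class `priming_report`.
#' @export
run_behavioral <- function(trials, config = analysis_config()) {
  word <- trials[trials$condition != "nonword" & !is.na(trials$rt_ms), ]
  conds <- intersect(WORD_CONDITIONS, unique(word$condition))
  condition_results <- list()
  for (cond in conds) {
    sub <- word[word$condition == cond, ]
    counts <- table(sub$prime_type)
    if (length(counts) < 2 || any(counts < 2)) {
      warning(sprintf("condition '%s' has < 2 trials per prime type: skipped",
                      cond))
      next
    }
    marginal <- mean(sub$rt_ms[sub$prime_type == "unrelated"]) -
      mean(sub$rt_ms[sub$prime_type == "related"])
    mc <- mc_pvalue_fixed_effect(sub, term = "prime_type", response = "rt_ms",
                                 n_iter = config$n_perm,
                                 seed = config$seed + match(cond, conds),
                                 scheme = config$perm_scheme)
    # model-based priming estimate: the prime-type coefficient conditions on
    # the crossed subject/item effects, so it stays unbiased when trial
    # rejection correlates with subject or item speed; the raw marginal
    # difference is kept as a diagnostic
    condition_results[[cond]] <- list(
      priming_ms = unname(mc$fit$coefficients["prime_type"]),
      marginal_priming_ms = marginal, t = unname(mc$t_obs),
      mc_p = mc$p, n_trials = nrow(sub))
  }
  interaction <- NULL
  ip <- word[word$condition %in% c("irregular", "pseudo_irregular"), ]
  if (all(c("irregular", "pseudo_irregular") %in% unique(ip$condition))) {
    x <- binary_indicator(ip$prime_type, "prime_type")
    z <- as.numeric(ip$condition == "pseudo_irregular")
    lr <- lrt_nested(ip$rt_ms, cbind(prime = x, pseudo = z),
                     cbind(prime = x, pseudo = z, prime_x_pseudo = x * z),
                     ip$subject_id, ip$item_id)
    interaction <- list(chi_sq = lr$chi_sq, df = lr$df, p = lr$p)
  }
  structure(list(analysis = "behavioral", conditions = condition_results,
                 prime_by_pseudo_irregularity = interaction,
                 n_perm = config$n_perm, seed = config$seed),
            class = "priming_report")
}

#' Orchestrated MEG analyses
#'
#' Executes the stage chain for a named analysis:
#' \describe{
#'   \item{`"anatomical_m170"`}{detects the evoked peak of the grand mean
#'     series within `peak_search_ms`, centers a 50 ms window on it, and runs
#'     the prime-type cluster permutation test pooled over the word
#'     conditions.}
#'   \item{`"m100"`}{same test over the fixed 50 ms window centered at
#'     100 ms (restrict with `conditions`, e.g. identity + regular).}
#'   \item{`"late"`}{prime-type test per condition over the fixed late
#'     window, plus the PrimeType x Pseudo-irregularity interaction on the
#'     irregular + pseudo-irregular trials.}
#'   \item{`"froi"`}{localizes the fROI on the localizer conditions
#'     (identity + regular) within the permitted masks, using a 50 ms window
#'     centered at the peak of their pooled priming-difference magnitude,
#'     then tests the irregular and pseudo-irregular conditions separately on
#'     the fROI-averaged time courses.}
#'   \item{`"albright"`}{orthogonalizes the support score against surface
#'     frequency at the item level, runs the score x prime-type interaction
#'     cluster test on the irregular trials, and the prime-type test within
#'     the high (> 0.5) and low (< 0.5) score bins.}
#' }
#'
#' @param x an [epoch_set()] (or a [source_epoch_set()] for `"froi"`).
#' @param trials aligned trial table.
#' @param analysis analysis name.
#' @param config an [analysis_config()].
#' @param conditions optional condition subset (pooled) for the epoch-based
#'   analyses; default all word conditions present.
#' @param window_ms optional explicit analysis window, overriding the
#'   configured rule (for `"albright"`, defaults to the fROI-style detected
#'   window when the epochs allow it).
#' @return a list of class `priming_report` (contents vary by analysis).
#' @export
run_meg_analysis <- function(x, trials,
                             analysis = c("anatomical_m170", "m100", "late",
                                          "froi", "albright"),
                             config = analysis_config(), conditions = NULL,
                             window_ms = NULL) {
  analysis <- match.arg(analysis)
  if (analysis == "froi") {
    return(run_froi_analysis(x, trials, config))
  }
  stopifnot(inherits(x, "epoch_set"))
  tr <- aligned_trials(x, trials)
  if (is.null(conditions))
    conditions <- intersect(WORD_CONDITIONS, unique(tr$condition))
  missing_cond <- setdiff(conditions, unique(tr$condition))
  if (length(missing_cond))
    stop("required conditions missing: ", paste(missing_cond, collapse = ", "))
  rows <- which(tr$condition %in% conditions)
  pooled <- subset_epochs(x, rows)

  if (analysis == "anatomical_m170") {
    gm <- mean_timecourse(pooled)
    peak <- find_peak_latency(gm, config$peak_search_ms, direction = "max")
    win <- if (is.null(window_ms))
      centered_window(as.numeric(peak), config$window_width_ms) else window_ms
    test <- permutation_test(pooled, trials, term = "prime_type",
                             window_ms = win, threshold = config$threshold,
                             n_perm = config$n_perm, seed = config$seed,
                             scheme = config$perm_scheme)
    return(structure(list(analysis = analysis, conditions = conditions,
                          window_provenance = "detected_peak",
                          peak_ms = as.numeric(peak), window_ms = win,
                          test = summarize_cluster_test(test),
                          cluster_test = test),
                     class = "priming_report"))
  }
  if (analysis == "m100") {
    win <- if (is.null(window_ms))
      centered_window(config$m100_center_ms, config$window_width_ms)
    else window_ms
    test <- permutation_test(pooled, trials, term = "prime_type",
                             window_ms = win, threshold = config$threshold,
                             n_perm = config$n_perm, seed = config$seed,
                             scheme = config$perm_scheme)
    return(structure(list(analysis = analysis, conditions = conditions,
                          window_provenance = "fixed_center_100",
                          window_ms = win,
                          test = summarize_cluster_test(test),
                          cluster_test = test),
                     class = "priming_report"))
  }
  # late window: per-condition tests + pseudo-irregularity interaction
  win <- if (is.null(window_ms)) config$late_window_ms else window_ms
  per_condition <- list()
  for (cond in conditions) {
    rows_c <- which(tr$condition == cond)
    test <- permutation_test(subset_epochs(x, rows_c), trials,
                             term = "prime_type", window_ms = win,
                             threshold = config$threshold,
                             n_perm = config$n_perm,
                             seed = config$seed + match(cond, conditions),
                             scheme = config$perm_scheme)
    per_condition[[cond]] <- summarize_cluster_test(test)
  }
  interaction <- NULL
  if (all(c("irregular", "pseudo_irregular") %in% conditions)) {
    rows_ip <- which(tr$condition %in% c("irregular", "pseudo_irregular"))
    tr_ip <- tr[rows_ip, , drop = FALSE]
    ep_ip <- epoch_set(x$data[rows_ip, , drop = FALSE], x$time_ms,
                       trial_index = seq_along(rows_ip),
                       sampling_rate_hz = x$sampling_rate_hz, units = x$units)
    tr_ip$pseudo <- as.numeric(tr_ip$condition == "pseudo_irregular")
    test <- permutation_test(ep_ip, tr_ip, term = "prime_type",
                             window_ms = win, threshold = config$threshold,
                             n_perm = config$n_perm, seed = config$seed + 11L,
                             scheme = config$perm_scheme,
                             interaction_with = "pseudo")
    interaction <- summarize_cluster_test(test)
  }
  structure(list(analysis = "late", conditions = conditions,
                 window_provenance = "fixed_late", window_ms = win,
                 per_condition = per_condition,
                 prime_by_pseudo_irregularity = interaction),
            class = "priming_report")
}

run_froi_analysis <- function(src, trials, config) {
  stopifnot(inherits(src, "source_epoch_set"))
  tr <- trials[src$trial_index, , drop = FALSE]
  need <- unique(c(config$froi_conditions, "irregular", "pseudo_irregular"))
  missing_cond <- setdiff(need, unique(tr$condition))
  if (length(missing_cond))
    stop("required conditions missing: ", paste(missing_cond, collapse = ", "))
  # peak of the localizer conditions' priming-difference magnitude, taken on
  # the mask-average series
  in_mask <- which(src$source_labels %in% config$froi_masks)
  if (!length(in_mask)) stop("no sources carry the requested mask labels")
  mask_mean <- apply(src$data[, in_mask, , drop = FALSE], c(1, 3), mean)
  loc <- tr$condition %in% config$froi_conditions
  diff_series <- colMeans(mask_mean[loc & tr$prime_type == "unrelated", ,
                                    drop = FALSE]) -
    colMeans(mask_mean[loc & tr$prime_type == "related", , drop = FALSE])
  attr(diff_series, "time_ms") <- src$time_ms
  peak <- find_peak_latency(diff_series, config$peak_search_ms,
                            direction = "absmax")
  win <- centered_window(as.numeric(peak), config$window_width_ms)
  froi <- localize_froi(src, trials, conditions = config$froi_conditions,
                        masks = config$froi_masks, window_ms = win)
  froi$peak_latency_ms <- as.numeric(peak)
  froi_epochs <- extract_froi_timecourses(src, froi)
  tests <- list()
  for (cond in c("irregular", "pseudo_irregular")) {
    rows_c <- which(tr$condition == cond)
    test <- permutation_test(subset_epochs(froi_epochs, rows_c), trials,
                             term = "prime_type", window_ms = win,
                             threshold = config$threshold,
                             n_perm = config$n_perm,
                             seed = config$seed + match(cond, need),
                             scheme = config$perm_scheme)
    tests[[cond]] <- summarize_cluster_test(test)
  }
  structure(list(analysis = "froi",
                 localizer_conditions = config$froi_conditions,
                 masks = config$froi_masks,
                 window_provenance = "detected_priming_peak",
                 peak_ms = as.numeric(peak), window_ms = win,
                 froi = list(sources = froi$sources,
                             peak_source = froi$peak_source),
                 per_condition = tests,
                 froi_definition = froi, froi_epochs = froi_epochs),
            class = "priming_report")
}

#' AlbrightScore analyses on fROI time courses
#'
#' @param epochs fROI-averaged [epoch_set()].
#' @param trials aligned trial table with `albright_score` and
#'   `log_surface_freq`.
#' @param config an [analysis_config()].
#' @param window_ms analysis window (typically the fROI window).
#' @return a `priming_report` with the interaction test and the high/low-bin
#'   prime-type tests.
#' @export
run_albright_analysis <- function(epochs, trials, config = analysis_config(),
                                  window_ms) {
  trials <- add_orthogonalized_albright(trials)
  inter <- interaction_analysis(epochs, trials, window_ms = window_ms,
                                threshold = config$threshold,
                                n_perm = config$n_perm, seed = config$seed)
  tr <- aligned_trials(epochs, trials)
  bins <- bin_albright(tr$albright_score)
  bin_tests <- list()
  for (bn in c("high", "low")) {
    rows <- which(tr$condition == "irregular" & !is.na(bins) & bins == bn)
    if (length(rows) < 4 ||
        length(unique(tr$prime_type[rows])) < 2) {
      warning(sprintf("bin '%s' has too few irregular trials: skipped", bn))
      next
    }
    test <- permutation_test(subset_epochs(epochs, rows), trials,
                             term = "prime_type", window_ms = window_ms,
                             threshold = config$threshold,
                             n_perm = config$n_perm,
                             seed = config$seed + match(bn, c("high", "low")),
                             scheme = config$perm_scheme)
    bin_tests[[bn]] <- summarize_cluster_test(test)
  }
  structure(list(analysis = "albright", window_ms = window_ms,
                 interaction = summarize_cluster_test(inter),
                 by_bin = bin_tests),
            class = "priming_report")
}

summarize_cluster_test <- function(x) {
  list(kind = x$series$kind, window_ms = x$window_ms,
       threshold = x$threshold, n_perm = x$n_perm, seed = x$seed,
       max_abs_mass = x$max_abs_mass, min_p = x$min_p,
       clusters = x$clusters)
}

#' @export
print.priming_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

#' Human-readable report text
#' @param report a `priming_report`.
#' @return character vector of lines.
#' @export
format_report <- function(report) {
  out <- sprintf("== %s analysis ==", report$analysis)
  fmt_test <- function(name, s) {
    lines <- sprintf("%s: window [%g, %g] ms, %d perms", name,
                     s$window_ms[1], s$window_ms[2], s$n_perm)
    if (nrow(s$clusters) == 0) {
      c(lines, "  no suprathreshold clusters (p = 1)")
    } else {
      c(lines, sprintf("  cluster %g-%g ms, mass %.2f, MC p = %.4g",
                       s$clusters$start_ms, s$clusters$end_ms,
                       s$clusters$mass, s$clusters$mc_p))
    }
  }
  if (report$analysis == "behavioral") {
    for (cond in names(report$conditions)) {
      r <- report$conditions[[cond]]
      out <- c(out, sprintf("%s: priming %.1f ms, t = %.2f, MC p = %.4g",
                            cond, r$priming_ms, r$t, r$mc_p))
    }
    if (!is.null(report$prime_by_pseudo_irregularity)) {
      i <- report$prime_by_pseudo_irregularity
      out <- c(out, sprintf(
        "PrimeType x Pseudo-irregularity: chi^2 = %.3g (df %d), p = %.3g",
        i$chi_sq, i$df, i$p))
    }
  } else {
    if (!is.null(report$peak_ms))
      out <- c(out, sprintf("detected peak: %g ms", report$peak_ms))
    if (!is.null(report$test)) out <- c(out, fmt_test("pooled", report$test))
    for (cond in names(report$per_condition))
      out <- c(out, fmt_test(cond, report$per_condition[[cond]]))
    if (!is.null(report$interaction))
      out <- c(out, fmt_test("score x prime interaction", report$interaction))
    for (bn in names(report$by_bin))
      out <- c(out, fmt_test(paste0(bn, "-score bin"), report$by_bin[[bn]]))
    if (!is.null(report$prime_by_pseudo_irregularity) &&
        report$analysis != "behavioral")
      out <- c(out, fmt_test("prime x pseudo-irregularity interaction",
                             report$prime_by_pseudo_irregularity))
  }
  out
}

#' Write a report as JSON (and optionally text)
#'
#' Serialization is canonical (fixed key order, full precision), so identical
#' configurations and seeds produce byte-identical files.
#'
#' @param report a `priming_report`.
#' @param json_path JSON output path.
#' @param text_path optional human-readable output path.
#' @export
write_report <- function(report, json_path, text_path = NULL) {
  ser <- unclass(report)
  ser$cluster_test <- NULL
  ser$froi_definition <- NULL
  ser$froi_epochs <- NULL
  jsonlite::write_json(ser, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, force = TRUE)
  if (!is.null(text_path)) writeLines(format_report(report), text_path)
  invisible(json_path)
}
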