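# Trial-level and subject-level filtering and signal conditioning.

#' Baseline-correct epochs
#'
#' Subtracts from every trial its mean amplitude over a pre-target interval,
#' so the returned epochs have per-trial baseline mean zero.
#'
#' @param epochs an [epoch_set()].
#' @param interval_ms baseline interval, default `c(-150, -50)` ms.
#' @return a baseline-corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, interval_ms = c(-150, -50)) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (interval_ms[1] < min(epochs$time_ms) - 1e-9 ||
      interval_ms[2] > max(epochs$time_ms) + 1e-9)
    stop("baseline interval lies outside the epoch window")
  idx <- time_window_idx(epochs$time_ms, interval_ms)
  base <- rowMeans(epochs$data[, idx, drop = FALSE])
  epochs$data <- epochs$data - base
  epochs
}

#' Zero-phase low-pass filter
#'
#' Forward-backward (zero-phase) 4th-order Butterworth low-pass. Passband
#' amplitudes are preserved and symmetric deflections keep their peak latency;
#' a sinusoid at twice the cutoff is attenuated by more than 20 dB.
#'
#' @param epochs an [epoch_set()].
#' @param cutoff_hz cutoff frequency; must be below Nyquist.
#' @param order filter order (applied twice by filtfilt).
#' @return a filtered `epoch_set`.
#' @export
lowpass_filter <- function(epochs, cutoff_hz = 40, order = 4) {
  stopifnot(inherits(epochs, "epoch_set"), cutoff_hz > 0)
  nyquist <- epochs$sampling_rate_hz / 2
  if (cutoff_hz >= nyquist)
    stop(sprintf("cutoff %g Hz must be below the Nyquist frequency %g Hz",
                 cutoff_hz, nyquist))
  bf <- signal::butter(order, cutoff_hz / nyquist, type = "low")
  epochs$data <- t(apply(epochs$data, 1, function(x) signal::filtfilt(bf, x)))
  epochs
}

#' Flag trials exceeding an absolute amplitude threshold
#'
#' A trial is rejected iff its maximum absolute amplitude within the check
#' window exceeds the threshold (strictly). Intended for raw-channel-mode
#' epochs in pT with the conventional +/-2.5 pT bound over (-150, +300) ms;
#' any threshold in the epochs' own units is accepted.
#'
#' @param raw_epochs an [epoch_set()].
#' @param threshold absolute amplitude bound (default 2.5).
#' @param window_ms check window (default `c(-150, 300)` ms).
#' @return logical vector, `TRUE` where the trial is rejected.
#' @export
reject_amplitude_outliers <- function(raw_epochs, threshold = 2.5,
                                      window_ms = c(-150, 300)) {
  stopifnot(inherits(raw_epochs, "epoch_set"), threshold > 0)
  idx <- time_window_idx(raw_epochs$time_ms, window_ms)
  apply(abs(raw_epochs$data[, idx, drop = FALSE]), 1, max) > threshold
}

#' Exclude subjects with outlying reaction-time distributions
#'
#' Computed on correct word-target trials: a subject is excluded iff their
#' mean RT exceeds the group mean of subject means by more than 2 SDs of the
#' subject means, or their RT SD exceeds the group mean of subject SDs by
#' more than 2 SDs of the subject SDs. Statistics include the candidate
#' subject (no leave-one-out).
#'
#' @param trials trial table with `rt_ms` and `accuracy`.
#' @return character vector of retained subject ids.
#' @export
exclude_subjects_by_rt <- function(trials) {
  word <- trials[trials$condition != "nonword" & trials$accuracy == 1 &
                   !is.na(trials$rt_ms), ]
  subj <- unique(as.character(trials$subject_id))
  if (length(subj) < 3)
    stop("subject exclusion needs at least 3 subjects")
  means <- tapply(word$rt_ms, as.character(word$subject_id), mean)
  sds <- tapply(word$rt_ms, as.character(word$subject_id), stats::sd)
  bad_mean <- means > mean(means) + 2 * stats::sd(means)
  bad_sd <- sds > mean(sds) + 2 * stats::sd(sds)
  keep <- names(means)[!(bad_mean | bad_sd)]
  sort(keep)
}

#' Trim outlier reaction-time trials
#'
#' Removes trials with `rt_ms < 300`, and trials whose RT exceeds the
#' cross-subject mean plus 2 SDs computed within the trial's condition.
#' Both statistics are computed once on the incoming table (single pass, not
#' iterated). Removed trials are recorded in a rejection log attached as the
#' `"rejection_log"` attribute (columns `trial_index`, `rule`, `value`),
#' writable with [write_rejection_log()].
#'
#' @param trials trial table with `rt_ms`.
#' @param floor_ms lower RT bound (default 300 ms).
#' @return the trimmed trial table with a `"rejection_log"` attribute.
#' @export
trim_rt_trials <- function(trials, floor_ms = 300) {
  stopifnot("rt_ms" %in% names(trials))
  rt <- trials$rt_ms
  cond <- as.character(trials$condition)
  mu <- tapply(rt, cond, mean, na.rm = TRUE)
  sd_ <- tapply(rt, cond, stats::sd, na.rm = TRUE)
  sd_[is.na(sd_)] <- 0
  upper <- mu[cond] + 2 * sd_[cond]
  too_fast <- !is.na(rt) & rt < floor_ms
  too_slow <- !is.na(rt) & !too_fast & rt > upper
  log <- data.frame(
    trial_index = c(which(too_fast), which(too_slow)),
    rule = rep(c("rt_floor", "rt_upper_2sd"),
               c(sum(too_fast), sum(too_slow))),
    value = rt[c(which(too_fast), which(too_slow))])
  log <- log[order(log$trial_index), ]
  rownames(log) <- NULL
  out <- trials[!(too_fast | too_slow), ]
  rownames(out) <- NULL
  attr(out, "rejection_log") <- log
  out
}

#' Write a trial rejection log as TSV
#' @param trials a table returned by [trim_rt_trials()], or a log data.frame.
#' @param path file path.
#' @export
write_rejection_log <- function(trials, path) {
  log <- attr(trials, "rejection_log")
  if (is.null(log)) log <- trials
  utils::write.table(log, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
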