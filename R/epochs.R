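#' Epoch container for ROI time courses
#'
#' An `epoch_set` holds signed source-estimate amplitudes for a set of trials
#' on a uniform time grid aligned to target onset. Rows of `data` correspond
#' 1:1 to the entries of `trial_index`, which index rows of the trial table
#' the epochs were simulated from (or ingested against).
#'
#' @param data numeric matrix, trials x timepoints.
#' @param time_ms strictly increasing uniform time grid in milliseconds.
#' @param trial_index integer vector aligning rows of `data` to trial-table rows.
#' @param sampling_rate_hz sampling rate; the grid spacing must equal
#'   `1000 / sampling_rate_hz` ms.
#' @param units character scalar, e.g. `"dspm"` for noise-normalized source
#'   estimates or `"pT"` for raw-channel-mode amplitudes.
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, time_ms, trial_index = seq_len(nrow(data)),
                      sampling_rate_hz = 1000, units = "dspm") {
  data <- as.matrix(data)
  stopifnot(is.numeric(data), length(time_ms) == ncol(data),
            length(trial_index) == nrow(data))
  if (length(time_ms) > 1) {
    dt <- diff(time_ms)
    if (any(dt <= 0)) stop("time_ms must be strictly increasing")
    if (max(abs(dt - 1000 / sampling_rate_hz)) > 1e-6)
      stop("time grid spacing must equal 1000 / sampling_rate_hz ms")
  }
  structure(list(data = data, time_ms = as.numeric(time_ms),
                 trial_index = as.integer(trial_index),
                 sampling_rate_hz = sampling_rate_hz, units = units),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials x %d timepoints [%g, %g] ms @ %g Hz (%s)\n",
              nrow(x$data), ncol(x$data), min(x$time_ms), max(x$time_ms),
              x$sampling_rate_hz, x$units))
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

#' Source-grid epoch container
#'
#' Holds trials x sources x timepoints signed source estimates on a shared
#' source grid, with an anatomical mask label per source. Sources live on an
#' abstract 1-D grid; adjacency for functional-ROI growth is |i - j| == 1.
#'
#' @param data numeric array, trials x sources x timepoints.
#' @param source_labels character vector, one anatomical mask name per source
#'   (e.g. `"fusiform"`, `"inferior_temporal"`, `"middle_temporal"`, `"other"`).
#' @inheritParams epoch_set
#' @return an object of class `source_epoch_set`.
#' @export
source_epoch_set <- function(data, source_labels, time_ms,
                             trial_index = seq_len(dim(data)[1]),
                             sampling_rate_hz = 1000, units = "dspm") {
  stopifnot(is.array(data), length(dim(data)) == 3,
            length(source_labels) == dim(data)[2],
            length(time_ms) == dim(data)[3],
            length(trial_index) == dim(data)[1])
  if (dim(data)[2] < 1) stop("source set must be nonempty")
  structure(list(data = data, source_labels = as.character(source_labels),
                 time_ms = as.numeric(time_ms),
                 trial_index = as.integer(trial_index),
                 sampling_rate_hz = sampling_rate_hz, units = units),
            class = "source_epoch_set")
}

#' @export
print.source_epoch_set <- function(x, ...) {
  cat(sprintf("<source_epoch_set> %d trials x %d sources x %d timepoints (%s)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$units))
  cat("  masks:", paste(sprintf("%s=%d", names(table(x$source_labels)),
                                table(x$source_labels)), collapse = ", "), "\n")
  invisible(x)
}

# Column indices of the time grid falling inside [from, to] ms (inclusive).
time_window_idx <- function(time_ms, window_ms) {
  stopifnot(length(window_ms) == 2)
  idx <- which(time_ms >= window_ms[1] - 1e-9 & time_ms <= window_ms[2] + 1e-9)
  if (length(idx) == 0)
    stop(sprintf("window [%g, %g] ms contains no samples of the epoch grid",
                 window_ms[1], window_ms[2]))
  idx
}

#' Write / read an epoch set as delimited text
#'
#' Plain-text round trip for small fixtures: a TSV whose first column is
#' `trial_index` and whose remaining columns are amplitudes named `t<ms>`.
#' Units and sampling rate are stored in a `#` header comment.
#'
#' @param epochs an `epoch_set`.
#' @param path file path.
#' @return `read_epochs_tsv` returns an `epoch_set`.
#' @export
write_epochs_tsv <- function(epochs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# epoch_set sampling_rate_hz=%g units=%s",
                     epochs$sampling_rate_hz, epochs$units), con)
  df <- data.frame(trial_index = epochs$trial_index, epochs$data)
  names(df) <- c("trial_index", sprintf("t%g", epochs$time_ms))
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_epochs_tsv
#' @export
read_epochs_tsv <- function(path) {
  hdr <- readLines(path, n = 1)
  fs <- as.numeric(sub(".*sampling_rate_hz=([0-9.eE+-]+).*", "\\1", hdr))
  units <- sub(".*units=(\\S+).*", "\\1", hdr)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  time_ms <- as.numeric(sub("^t", "", names(df)[-1]))
  epoch_set(as.matrix(df[, -1, drop = FALSE]), time_ms,
            trial_index = df$trial_index, sampling_rate_hz = fs, units = units)
}

#' Read / write a trial table as delimited text
#'
#' One row per trial, UTF-8, tab-separated with a header. Missing reaction
#' times (rejected trials) are empty fields.
#'
#' @param trials a trial-table `data.frame`.
#' @param path file path.
#' @export
write_trial_table <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  df <- utils::read.delim(path, na.strings = "", stringsAsFactors = FALSE)
  df$subject_id <- factor(df$subject_id)
  df$item_id <- factor(df$item_id)
  df
}
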