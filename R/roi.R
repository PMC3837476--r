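# Analysis-window selection from evoked peaks, and functional-ROI
# localization of the priming effect on the source grid.

#' Mean time course over a trial selection
#'
#' @param epochs an [epoch_set()].
#' @param selector logical or integer vector selecting rows of the epoch
#'   data (default all trials).
#' @return numeric series (one value per timepoint) with the time grid in
#'   the `"time_ms"` attribute.
#' @export
mean_timecourse <- function(epochs, selector = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.null(selector)) selector <- seq_len(nrow(epochs$data))
  sub <- epochs$data[selector, , drop = FALSE]
  if (nrow(sub) == 0) stop("selector matches no trials")
  out <- colMeans(sub)
  attr(out, "time_ms") <- epochs$time_ms
  out
}

#' Latency of the extremum of a series within a search window
#'
#' Ties are broken toward the earliest timepoint. If the extremum sits on the
#' window edge, the returned latency carries attribute `at_edge = TRUE` and a
#' message is emitted, since an edge extremum suggests the true peak lies
#' outside the searched window.
#'
#' @param series numeric series (e.g. from [mean_timecourse()]); its time
#'   grid is taken from the `"time_ms"` attribute unless `time_ms` is given.
#' @param search_window_ms window to search.
#' @param direction `"max"`, `"min"`, or `"absmax"`.
#' @param time_ms optional explicit time grid.
#' @return peak latency in ms.
#' @export
find_peak_latency <- function(series, search_window_ms,
                              direction = c("max", "min", "absmax"),
                              time_ms = NULL) {
  direction <- match.arg(direction)
  if (is.null(time_ms)) time_ms <- attr(series, "time_ms")
  stopifnot(!is.null(time_ms), length(time_ms) == length(series))
  idx <- time_window_idx(time_ms, search_window_ms)
  v <- as.numeric(series)[idx]
  if (max(v) - min(v) < 1e-24 && length(v) > 1)
    stop("series is constant within the search window: no peak")
  key <- switch(direction, max = v, min = -v, absmax = abs(v))
  k <- which.max(key)  # which.max returns the earliest tie
  lat <- time_ms[idx[k]]
  if (k == 1 || k == length(v)) {
    message(sprintf(
      "peak at %g ms lies on the edge of the search window [%g, %g] ms",
      lat, search_window_ms[1], search_window_ms[2]))
    attr(lat, "at_edge") <- TRUE
  }
  lat
}

#' Analysis window centered on a peak
#' @param peak_ms peak latency.
#' @param width_ms window width (default 50 ms).
#' @return `c(start_ms, end_ms)` = peak +/- width/2.
#' @export
centered_window <- function(peak_ms, width_ms = 50) {
  stopifnot(width_ms > 0)
  c(peak_ms - width_ms / 2, peak_ms + width_ms / 2)
}

#' Functional-ROI definition
#'
#' @param sources integer source indices forming the fROI.
#' @param peak_source index of the peak-effect source (must lie in `sources`).
#' @param peak_latency_ms latency used to anchor the localizer window.
#' @param conditions_used localizer condition set.
#' @param window_used_ms window the per-source difference was averaged over.
#' @return an object of class `froi_definition`.
#' @export
froi_definition <- function(sources, peak_source, peak_latency_ms,
                            conditions_used, window_used_ms) {
  sources <- as.integer(sources)
  stopifnot(length(sources) >= 1, peak_source %in% sources)
  structure(list(sources = sources, peak_source = as.integer(peak_source),
                 peak_latency_ms = peak_latency_ms,
                 conditions_used = conditions_used,
                 window_used_ms = window_used_ms),
            class = "froi_definition")
}

#' @export
print.froi_definition <- function(x, ...) {
  cat(sprintf(
    "<froi_definition> %d sources (peak %d), window [%g, %g] ms, localizer: %s\n",
    length(x$sources), x$peak_source, x$window_used_ms[1], x$window_used_ms[2],
    paste(x$conditions_used, collapse = "+")))
  invisible(x)
}

#' Localize a functional ROI around the peak facilitatory priming effect
#'
#' For each source inside the permitted anatomical masks, computes the
#' unrelated-minus-related mean difference over the localizer conditions,
#' averaged over the window, and signs it by the source's evoked-response
#' polarity (the sign of the evoked mean at its largest absolute value in the
#' window), so that "facilitatory" means a reduction of |activity| for
#' related primes regardless of the source's raw polarity. The fROI is the
#' peak facilitatory source plus, under the default extent rule, every
#' mask-internal source whose facilitatory difference is at least half the
#' peak's, restricted to the grid-adjacency connected component containing
#' the peak.
#'
#' @param src a [source_epoch_set()].
#' @param trials aligned trial table.
#' @param conditions localizer conditions (default identity + regular).
#' @param masks permitted anatomical masks (default fusiform +
#'   inferior_temporal).
#' @param window_ms averaging window.
#' @param extent_fraction fraction of the peak facilitatory difference a
#'   source must reach to join the fROI (default 0.5).
#' @return a [froi_definition()].
#' @export
localize_froi <- function(src, trials,
                          conditions = c("identity", "regular"),
                          masks = c("fusiform", "inferior_temporal"),
                          window_ms, extent_fraction = 0.5) {
  stopifnot(inherits(src, "source_epoch_set"))
  tr <- trials[src$trial_index, , drop = FALSE]
  missing_cond <- setdiff(conditions, unique(tr$condition))
  if (length(missing_cond))
    stop("conditions absent from trials: ", paste(missing_cond, collapse = ", "))
  if (!any(src$source_labels %in% masks))
    stop("no sources carry the requested mask labels")
  idx <- time_window_idx(src$time_ms, window_ms)
  sel <- tr$condition %in% conditions
  rel <- sel & tr$prime_type == "related"
  unr <- sel & tr$prime_type == "unrelated"
  if (!any(rel) || !any(unr))
    stop("localizer conditions must include related and unrelated trials")
  n_src <- dim(src$data)[2]
  facil <- rep(NA_real_, n_src)
  in_mask <- src$source_labels %in% masks
  for (s in which(in_mask)) {
    win <- src$data[, s, idx, drop = FALSE][, 1, ]
    evoked <- colMeans(win[sel, , drop = FALSE])
    pol <- sign(evoked[which.max(abs(evoked))])
    if (pol == 0) pol <- 1
    diff_s <- mean(win[unr, , drop = FALSE]) - mean(win[rel, , drop = FALSE])
    facil[s] <- pol * diff_s
  }
  if (max(facil, na.rm = TRUE) <= 0)
    stop("no facilitatory priming effect found within the masks")
  peak <- which.max(facil)
  eligible <- which(in_mask & !is.na(facil) &
                      facil >= extent_fraction * facil[peak])
  # connected component of the 1-D source grid containing the peak
  comp <- peak
  repeat {
    grown <- unique(c(comp, intersect(c(comp - 1L, comp + 1L), eligible)))
    if (length(grown) == length(comp)) break
    comp <- grown
  }
  froi_definition(sort(comp), peak, mean(range(src$time_ms[idx])),
                  conditions, range(src$time_ms[idx]))
}

#' Average source-grid epochs over a functional ROI
#'
#' @param src a [source_epoch_set()].
#' @param froi a [froi_definition()].
#' @return an [epoch_set()] whose per-trial series is the mean over the fROI
#'   sources.
#' @export
extract_froi_timecourses <- function(src, froi) {
  stopifnot(inherits(src, "source_epoch_set"),
            inherits(froi, "froi_definition"))
  if (max(froi$sources) > dim(src$data)[2])
    stop("fROI sources outside the source grid")
  sub <- src$data[, froi$sources, , drop = FALSE]
  data <- apply(sub, c(1, 3), mean)
  epoch_set(data, src$time_ms, trial_index = src$trial_index,
            sampling_rate_hz = src$sampling_rate_hz, units = src$units)
}

#' Serialize an fROI definition
#' @param froi a [froi_definition()].
#' @param path file path; `write_froi_label` writes one source index per line.
#' @export
write_froi_json <- function(froi, path) {
  jsonlite::write_json(unclass(froi), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_froi_json
#' @export
write_froi_label <- function(froi, path) {
  writeLines(as.character(froi$sources), path)
  invisible(path)
}
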