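# Gradient morphophonological support scores (AlbrightScore): ingestion,
# orthogonalization against surface frequency, high/low binning, and the
# score x prime-type interaction analysis.

#' Orthogonalize a covariate against a confound
#'
#' Residuals of the least-squares regression of `x` on `[1, covariate]`:
#' the returned vector has zero mean and zero sample correlation with the
#' confound, so any retained effect is uncontaminated by it.
#'
#' @param x numeric vector.
#' @param covariate numeric vector of equal length; must be non-constant.
#' @return residual vector.
#' @export
orthogonalize <- function(x, covariate) {
  stopifnot(length(x) == length(covariate))
  if (stats::var(covariate) < 1e-24)
    stop("covariate is constant: orthogonalization undefined")
  as.numeric(stats::resid(stats::lm(x ~ covariate)))
}

#' Bin support scores into high/low with a strict cutpoint
#'
#' Scores strictly above the cutpoint are `"high"`, strictly below `"low"`;
#' scores exactly at the cutpoint are `"excluded"` (the strict inequalities
#' leave the boundary unassigned).
#'
#' @param scores numeric vector in `[0, 1]`.
#' @param cutpoint boundary (default 0.5).
#' @return factor with levels high, low, excluded.
#' @export
bin_albright <- function(scores, cutpoint = 0.5) {
  stopifnot(all(scores >= 0 & scores <= 1, na.rm = TRUE))
  out <- ifelse(is.na(scores), NA,
                ifelse(scores > cutpoint, "high",
                       ifelse(scores < cutpoint, "low", "excluded")))
  factor(out, levels = c("high", "low", "excluded"))
}

#' Read item support scores from a two-column delimited file
#'
#' @param path delimited file with columns `item_id`, `albright_score`.
#' @return data.frame with those columns.
#' @export
read_albright_scores <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("item_id", "albright_score") %in% names(df)))
  df
}

#' Attach item-level orthogonalized scores to a trial table
#'
#' Orthogonalization is computed at the item level (each item contributes one
#' score and one frequency, regardless of how many trials present it) and the
#' residual is broadcast back to trials as `albright_score_o`.
#'
#' @param trials trial table with `albright_score` and `log_surface_freq`.
#' @return the trial table with an `albright_score_o` column (NA where the
#'   score is undefined).
#' @export
add_orthogonalized_albright <- function(trials) {
  items <- unique(trials[!is.na(trials$albright_score),
                         c("item_id", "albright_score", "log_surface_freq")])
  if (nrow(items) < 3) stop("too few scored items to orthogonalize")
  items$albright_score_o <- orthogonalize(items$albright_score,
                                          items$log_surface_freq)
  m <- match(trials$item_id, items$item_id)
  trials$albright_score_o <- items$albright_score_o[m]
  trials
}

#' Score x prime-type interaction cluster test
#'
#' Runs the square-root-chi-squared interaction variant of the cluster-mass
#' permutation test on the irregular-condition trials: at each timepoint the
#' ML fits with {prime type, score} versus {prime type, score, interaction}
#' are compared, and prime-type labels are permuted within subject while the
#' (item-bound) score stays fixed, breaking only their assignment.
#'
#' @param epochs an [epoch_set()] (e.g. fROI time courses).
#' @param trials aligned trial table carrying `albright_score_o` (see
#'   [add_orthogonalized_albright()]).
#' @param score_term moderator column (default `"albright_score_o"`).
#' @param factor_term permutable factor (default `"prime_type"`).
#' @param condition condition to restrict to (default `"irregular"`).
#' @param window_ms analysis window.
#' @param threshold cluster-forming threshold on sqrt(chi^2) (default 1.96,
#'   i.e. chi^2 > 3.84, p < 0.05).
#' @param n_perm,seed,mode passed to [permutation_test()].
#' @return a `cluster_test`.
#' @export
interaction_analysis <- function(epochs, trials,
                                 score_term = "albright_score_o",
                                 factor_term = "prime_type",
                                 condition = "irregular",
                                 window_ms, threshold = 1.96,
                                 n_perm = 10000, seed = 1L, mode = "score") {
  tr <- aligned_trials(epochs, trials)
  keep <- which(tr$condition == condition & !is.na(tr[[score_term]]))
  if (length(keep) < 4)
    stop(sprintf("too few '%s' trials with a defined score", condition))
  sub_epochs <- epoch_set(epochs$data[keep, , drop = FALSE], epochs$time_ms,
                          trial_index = seq_along(keep),
                          sampling_rate_hz = epochs$sampling_rate_hz,
                          units = epochs$units)
  sub_trials <- tr[keep, , drop = FALSE]
  if (stats::var(sub_trials[[score_term]]) < 1e-24)
    stop(sprintf("'%s' is constant across items: no interaction variation",
                 score_term))
  permutation_test(sub_epochs, sub_trials, term = factor_term,
                   window_ms = window_ms, threshold = threshold,
                   n_perm = n_perm, seed = seed, mode = mode,
                   interaction_with = score_term)
}
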