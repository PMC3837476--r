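# Millisecond-wise statistics, temporal cluster-mass (sum-of-t) statistics,
# and max-statistic permutation correction. The inferential engine: at each
# timepoint a crossed random-intercept LMM gives a t-value (or, for
# interactions, a likelihood-ratio chi^2 whose square root is used); runs of
# consecutive suprathreshold same-sign values form clusters whose mass is the
# sum of member statistics; the largest absolute mass is referred to its
# permutation distribution.

#' Construct a per-timepoint statistic series
#' @param values numeric statistic per timepoint.
#' @param time_ms matching time grid.
#' @param kind `"t"` (signed) or `"sqrt_chisq"` (non-negative).
#' @return an object of class `stat_series`.
#' @export
stat_series <- function(values, time_ms, kind = c("t", "sqrt_chisq")) {
  kind <- match.arg(kind)
  stopifnot(length(values) == length(time_ms))
  if (kind == "sqrt_chisq" && any(values < -1e-12))
    stop("sqrt_chisq series must be non-negative")
  structure(list(values = as.numeric(values), time_ms = as.numeric(time_ms),
                 kind = kind), class = "stat_series")
}

#' @export
print.stat_series <- function(x, ...) {
  cat(sprintf("<stat_series:%s> %d timepoints [%g, %g] ms, max |stat| %.3f\n",
              x$kind, length(x$values), min(x$time_ms), max(x$time_ms),
              max(abs(x$values))))
  invisible(x)
}

# Trial-table rows aligned to the epoch rows.
aligned_trials <- function(epochs, trials) {
  if (max(epochs$trial_index) > nrow(trials))
    stop("epochs are not aligned to the trial table")
  trials[epochs$trial_index, , drop = FALSE]
}

# REML t-value and variance components per timepoint, sharing a fitted model
# template across timepoints via refit(). Failed timepoints yield t = 0 and
# NA components, and are recorded.
pointwise_lmm_engine <- function(Y, x01, subject, item) {
  nt <- ncol(Y)
  tvals <- numeric(nt)
  vc <- matrix(NA_real_, nt, 3,
               dimnames = list(NULL, c("subject", "item", "residual")))
  failed <- integer(0)
  df <- data.frame(.y = Y[, 1], .x = x01, .subject = factor(subject),
                   .item = factor(item))
  template <- NULL
  for (j in seq_len(nt)) {
    y <- Y[, j]
    if (stats::var(y) < 1e-24) { tvals[j] <- 0; next }
    fm <- tryCatch(suppressMessages(withCallingHandlers({
      if (is.null(template)) {
        df$.y <- y
        template <- lme4::lmer(
          .y ~ .x + (1 | .subject) + (1 | .item), data = df, REML = TRUE,
          control = lme4::lmerControl(calc.derivs = FALSE,
                                      check.conv.singular = "ignore"))
        template
      } else lme4::refit(template, newresp = y)
    }, warning = function(w) invokeRestart("muffleWarning"))),
    error = function(e) NULL)
    if (is.null(fm)) { tvals[j] <- 0; failed <- c(failed, j); next }
    est <- lme4::fixef(fm)[".x"]
    se <- sqrt(diag(as.matrix(stats::vcov(fm))))[2]
    vcs <- lme4::VarCorr(fm)
    vc[j, ] <- c(as.numeric(vcs$.subject), as.numeric(vcs$.item),
                 attr(vcs, "sc")^2)
    tvals[j] <- est / se
  }
  list(t = tvals, vc = vc, failed = failed)
}

#' Millisecond-wise fixed-effect t-values over a time window
#'
#' At each timepoint of the window, fits the crossed random-intercept LMM
#' with the amplitude at that timepoint as response and the two-level term as
#' fixed effect, and emits the term's t-value. Timepoints where the fit fails
#' are emitted as 0 and listed in the `"failed"` attribute; the per-timepoint
#' variance components are attached as the `"vc"` attribute.
#'
#' @param epochs an [epoch_set()].
#' @param trials trial table the epochs are aligned to.
#' @param term name of a two-level factor column (default `"prime_type"`).
#' @param window_ms analysis window.
#' @return a [stat_series()] of kind `"t"`.
#' @export
pointwise_stats <- function(epochs, trials, term = "prime_type", window_ms) {
  stopifnot(inherits(epochs, "epoch_set"))
  tr <- aligned_trials(epochs, trials)
  idx <- time_window_idx(epochs$time_ms, window_ms)
  x01 <- binary_indicator(tr[[term]], term)
  res <- pointwise_lmm_engine(epochs$data[, idx, drop = FALSE], x01,
                              tr$subject_id, tr$item_id)
  out <- stat_series(res$t, epochs$time_ms[idx], kind = "t")
  attr(out, "vc") <- res$vc
  attr(out, "failed") <- res$failed
  out
}

# ML variance components of the full interaction model per timepoint.
pointwise_interaction_vc <- function(Y, x01, b, subject, item) {
  nt <- ncol(Y)
  vc <- matrix(NA_real_, nt, 3)
  df <- data.frame(.y = Y[, 1], .x = x01, .b = b, .subject = factor(subject),
                   .item = factor(item))
  template <- NULL
  for (j in seq_len(nt)) {
    y <- Y[, j]
    if (stats::var(y) < 1e-24) next
    fm <- tryCatch(suppressMessages(withCallingHandlers({
      if (is.null(template)) {
        df$.y <- y
        template <- lme4::lmer(
          .y ~ .x * .b + (1 | .subject) + (1 | .item), data = df, REML = FALSE,
          control = lme4::lmerControl(calc.derivs = FALSE,
                                      check.conv.singular = "ignore"))
        template
      } else lme4::refit(template, newresp = y)
    }, warning = function(w) invokeRestart("muffleWarning"))),
    error = function(e) NULL)
    if (is.null(fm)) next
    vcs <- lme4::VarCorr(fm)
    vc[j, ] <- c(as.numeric(vcs$.subject), as.numeric(vcs$.item),
                 attr(vcs, "sc")^2)
  }
  vc
}

#' Millisecond-wise interaction statistics (square root of chi-squared)
#'
#' At each timepoint, compares the ML fits with fixed effects {a, b} versus
#' {a, b, a:b} by likelihood-ratio test and emits the square root of the
#' chi-squared statistic (1 df), so the conventional 1.96 threshold
#' corresponds to chi-squared > 3.84, p < 0.05.
#'
#' @param epochs an [epoch_set()].
#' @param trials aligned trial table.
#' @param term_a two-level factor column (permutable factor, e.g. prime type).
#' @param term_b numeric moderator column (e.g. an orthogonalized covariate).
#' @param window_ms analysis window.
#' @return a [stat_series()] of kind `"sqrt_chisq"`.
#' @export
pointwise_interaction_stats <- function(epochs, trials, term_a = "prime_type",
                                        term_b, window_ms) {
  stopifnot(inherits(epochs, "epoch_set"))
  tr <- aligned_trials(epochs, trials)
  idx <- time_window_idx(epochs$time_ms, window_ms)
  x01 <- binary_indicator(tr[[term_a]], term_a)
  b <- tr[[term_b]]
  if (!is.numeric(b)) b <- binary_indicator(b, term_b)
  if (stats::var(b) < 1e-24)
    stop(sprintf("term '%s' is constant: no interaction variation", term_b))
  Y <- epochs$data[, idx, drop = FALSE]
  vals <- vapply(seq_len(ncol(Y)), function(j) {
    y <- Y[, j]
    if (stats::var(y) < 1e-24) return(0)
    red <- cbind(a = x01, b = b)
    full <- cbind(a = x01, b = b, ab = x01 * b)
    lr <- tryCatch(lrt_nested(y, red, full, tr$subject_id, tr$item_id),
                   error = function(e) NULL)
    if (is.null(lr)) 0 else sqrt(lr$chi_sq)
  }, numeric(1))
  out <- stat_series(vals, epochs$time_ms[idx], kind = "sqrt_chisq")
  attr(out, "vc") <- pointwise_interaction_vc(Y, x01, b,
                                              tr$subject_id, tr$item_id)
  out
}

#' Find temporal clusters of suprathreshold statistics
#'
#' Maximal runs of consecutive timepoints with values strictly greater than
#' `threshold` (positive clusters) or strictly less than `-threshold`
#' (negative clusters; only positive clusters exist for `sqrt_chisq` series).
#' Values exactly at the threshold are not members. The mass of a cluster is
#' the sum of its member statistics.
#'
#' @param series a [stat_series()] (or a bare numeric vector, taken as a t
#'   series on an index grid).
#' @param threshold cluster-forming threshold (> 0), default 1.96.
#' @return data.frame with columns `start_ms`, `end_ms`, `start_idx`,
#'   `end_idx`, `sign`, `mass`; zero rows when no cluster exists.
#' @export
find_clusters <- function(series, threshold = 1.96) {
  stopifnot(threshold > 0)
  if (is.numeric(series)) series <- stat_series(series, seq_along(series))
  v <- series$values
  state <- integer(length(v))
  state[v > threshold] <- 1L
  if (series$kind != "sqrt_chisq") state[v < -threshold] <- -1L
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values != 0
  out <- data.frame(
    start_ms = series$time_ms[starts[keep]],
    end_ms = series$time_ms[ends[keep]],
    start_idx = starts[keep], end_idx = ends[keep],
    sign = r$values[keep],
    mass = vapply(which(keep), function(k)
      sum(v[starts[k]:ends[k]]), numeric(1)))
  rownames(out) <- NULL
  out
}

# Largest absolute cluster mass of a series (0 when no cluster).
max_cluster_mass <- function(v, threshold, two_sided = TRUE) {
  state <- (v > threshold)
  if (two_sided) {
    best <- 0
    r <- rle(ifelse(v > threshold, 1L, ifelse(v < -threshold, -1L, 0L)))
    ends <- cumsum(r$lengths)
    for (k in which(r$values != 0L)) {
      m <- abs(sum(v[(ends[k] - r$lengths[k] + 1):ends[k]]))
      if (m > best) best <- m
    }
    best
  } else {
    if (!any(state)) return(0)
    r <- rle(state)
    ends <- cumsum(r$lengths)
    max(vapply(which(r$values), function(k)
      sum(v[(ends[k] - r$lengths[k] + 1):ends[k]]), numeric(1)))
  }
}

#' Cluster-mass permutation test of a priming (or interaction) effect
#'
#' Computes the observed millisecond-wise statistic series and its clusters,
#' then recomputes the maximum absolute cluster mass under `n_perm` random
#' relabelings of the independent variable. By default labels are permuted
#' within subject (preserving each subject's related/unrelated counts, the
#' scheme under which the subject random effect is ancillary); `"free"`
#' permutes across the whole table. Each cluster's Monte-Carlo p-value uses
#' the add-one estimator `(1 + #\{null max >= |mass|\}) / (1 + n_perm)`; an
#' observation with no clusters is reported with `min_p = 1`.
#'
#' Two computation modes: `"score"` (default) freezes each timepoint's
#' REML/ML variance components from the observed fit and evaluates both the
#' observed and the permuted-label statistics by generalized least squares
#' under that covariance (for the t statistic this reproduces the
#' mixed-model t exactly; for the interaction the Wald chi^2 stands in for
#' the LRT, with which it coincides at fixed covariance); `"refit"` re-runs
#' the full mixed-model fit for every permutation and timepoint (validation
#' only; impractical beyond small fixtures).
#'
#' @param epochs an [epoch_set()].
#' @param trials aligned trial table.
#' @param term two-level factor column to test (and permute).
#' @param window_ms analysis window.
#' @param threshold cluster-forming threshold (default 1.96).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @param scheme `"within_subject"` (default) or `"free"`.
#' @param mode `"score"` (default) or `"refit"`.
#' @param interaction_with optional numeric moderator column name; when given
#'   the test is the sqrt-chi-squared interaction variant: `term` is permuted
#'   while the moderator stays fixed, breaking only their assignment.
#' @return an object of class `cluster_test`: `clusters` (with `mc_p`),
#'   `max_abs_mass`, `min_p`, `null_distribution`, `series`, `threshold`,
#'   `n_perm`, `seed`, `scheme`, `mode`.
#' @export
permutation_test <- function(epochs, trials, term = "prime_type", window_ms,
                             threshold = 1.96, n_perm = 10000, seed = 1L,
                             scheme = c("within_subject", "free"),
                             mode = c("score", "refit"),
                             interaction_with = NULL) {
  scheme <- match.arg(scheme)
  mode <- match.arg(mode)
  stopifnot(n_perm >= 1)
  tr <- aligned_trials(epochs, trials)
  idx <- time_window_idx(epochs$time_ms, window_ms)
  time_ms <- epochs$time_ms[idx]
  Y <- epochs$data[, idx, drop = FALSE]
  nt <- ncol(Y)
  x01 <- binary_indicator(tr[[term]], term)
  b <- NULL
  if (!is.null(interaction_with)) {
    b <- tr[[interaction_with]]
    if (!is.numeric(b)) b <- binary_indicator(b, interaction_with)
  }
  two_sided <- is.null(b)

  Xp <- with_seed(seed,
                  permute_labels(x01, tr$subject_id, n_perm, scheme))
  Xall <- cbind(x01, Xp)  # column 1 = observed labels

  if (mode == "score") {
    if (two_sided) {
      fit0 <- pointwise_lmm_engine(Y, x01, tr$subject_id, tr$item_id)
      vc <- fit0$vc
    } else {
      vc <- pointwise_interaction_vc(Y, x01, b, tr$subject_id, tr$item_id)
    }
    prep <- gls_prepare(tr$subject_id, tr$item_id, Xall, b = b)
    XtY <- crossprod(Xall, Y)
    stats_mat <- matrix(0, ncol(Xall), nt)
    for (j in seq_len(nt)) {
      if (any(is.na(vc[j, ])) || stats::var(Y[, j]) < 1e-24) next
      stats_mat[, j] <- if (two_sided)
        gls_t_at_vc(prep, vc[j, ], Y[, j], xty = XtY[, j])
      else
        sqrt(gls_chisq_at_vc(prep, vc[j, ], Y[, j]))
    }
  } else {
    stats_mat <- matrix(0, ncol(Xall), nt)
    for (p in seq_len(ncol(Xall))) {
      xp <- Xall[, p]
      for (j in seq_len(nt)) {
        y <- Y[, j]
        if (stats::var(y) < 1e-24) next
        stats_mat[p, j] <- tryCatch({
          if (two_sided) {
            f <- fit_lmm(y, cbind(x = xp), tr$subject_id, tr$item_id, "REML")
            f$t[["x"]]
          } else {
            lr <- lrt_nested(y, cbind(a = xp, b = b),
                             cbind(a = xp, b = b, ab = xp * b),
                             tr$subject_id, tr$item_id)
            sqrt(lr$chi_sq)
          }
        }, error = function(e) 0)
      }
    }
  }

  kind <- if (two_sided) "t" else "sqrt_chisq"
  obs_series <- stat_series(stats_mat[1, ], time_ms, kind = kind)
  clusters <- find_clusters(obs_series, threshold)
  null_dist <- vapply(seq_len(n_perm), function(p)
    max_cluster_mass(stats_mat[p + 1, ], threshold, two_sided), numeric(1))
  if (nrow(clusters)) {
    clusters$mc_p <- vapply(clusters$mass, function(m)
      (1 + sum(null_dist >= abs(m) - 1e-12)) / (1 + n_perm), numeric(1))
  } else {
    clusters$mc_p <- numeric(0)
  }
  structure(list(clusters = clusters,
                 max_abs_mass = if (nrow(clusters)) max(abs(clusters$mass)) else 0,
                 min_p = if (nrow(clusters)) min(clusters$mc_p) else 1,
                 null_distribution = null_dist, series = obs_series,
                 threshold = threshold, n_perm = n_perm, seed = seed,
                 scheme = scheme, mode = mode,
                 term = term, interaction_with = interaction_with,
                 window_ms = range(time_ms)),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test:%s> window [%g, %g] ms, threshold %g, %d perms\n",
              x$series$kind, x$window_ms[1], x$window_ms[2], x$threshold,
              x$n_perm))
  if (nrow(x$clusters) == 0) {
    cat("  no suprathreshold clusters (p = 1)\n")
  } else {
    df <- x$clusters
    for (k in seq_len(nrow(df)))
      cat(sprintf("  cluster %d: %g-%g ms, sign %+d, mass %.2f, MC p = %.4g\n",
                  k, df$start_ms[k], df$end_ms[k], df$sign[k], df$mass[k],
                  df$mc_p[k]))
  }
  invisible(x)
}

#' Serialize a cluster test result to JSON
#' @param x a `cluster_test`.
#' @param path file path.
#' @param include_null also write the permutation null distribution.
#' @export
write_cluster_test <- function(x, path, include_null = FALSE) {
  out <- list(kind = x$series$kind, window_ms = x$window_ms,
              threshold = x$threshold, n_perm = x$n_perm, seed = x$seed,
              scheme = x$scheme, mode = x$mode,
              max_abs_mass = x$max_abs_mass, min_p = x$min_p,
              clusters = x$clusters)
  if (include_null) out$null_distribution <- x$null_distribution
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
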