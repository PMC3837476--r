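# Crossed random-intercept linear mixed models: single fits, nested
# likelihood-ratio tests, and Monte-Carlo (permutation) p-values for a
# two-level fixed effect.

#' Fit a Gaussian LMM with crossed subject and item random intercepts
#'
#' Thin, contract-checked wrapper around a crossed random-intercept
#' `lme4::lmer` fit: `response ~ fixed terms + (1 | subject) + (1 | item)`.
#' An intercept is always included; `fixed` supplies the named non-intercept
#' columns of the design matrix (or `NULL` for an intercept-only model).
#'
#' @param response numeric vector.
#' @param fixed numeric matrix with named columns, or `NULL`.
#' @param subject,item grouping vectors (coerced to factor), each with at
#'   least 2 levels.
#' @param method `"REML"` (reporting t-values) or `"ML"` (for
#'   likelihood-ratio comparison of fixed effects).
#' @return an object of class `lmm_fit`: `coefficients`, `se`, `t`
#'   (estimate/SE, used without a degrees-of-freedom correction), `vc`
#'   (subject, item, residual variances), `logLik`, `method`, `converged`,
#'   `n`, and the underlying `merMod` as `$model` (NULL for degenerate fits).
#' @export
fit_lmm <- function(response, fixed = NULL, subject, item,
                    method = c("REML", "ML")) {
  method <- match.arg(method)
  subject <- factor(subject)
  item <- factor(item)
  n <- length(response)
  stopifnot(length(subject) == n, length(item) == n)
  if (nlevels(subject) < 2 || nlevels(item) < 2)
    stop("need at least 2 levels each of subject and item")
  if (!is.null(fixed)) {
    fixed <- as.matrix(fixed)
    if (is.null(colnames(fixed)) || any(colnames(fixed) == ""))
      stop("fixed-effect columns must be named")
    X <- cbind("(Intercept)" = 1, fixed)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
      stop("rank-deficient fixed-effect design; collinear term(s): ",
           paste(bad, collapse = ", "))
    }
  }
  terms <- colnames(fixed)
  if (stats::var(response) < 1e-24) {
    # constant response: exact degenerate solution, all variances zero
    coefs <- c("(Intercept)" = response[1],
               stats::setNames(rep(0, length(terms)), terms))
    return(structure(list(coefficients = coefs,
                          se = stats::setNames(rep(NA_real_, length(coefs)),
                                               names(coefs)),
                          t = stats::setNames(rep(0, length(coefs)),
                                              names(coefs)),
                          vc = c(subject = 0, item = 0, residual = 0),
                          logLik = NA_real_, method = method,
                          converged = TRUE, degenerate = TRUE, n = n,
                          model = NULL),
                     class = "lmm_fit"))
  }
  df <- data.frame(.y = response, .subject = subject, .item = item)
  rhs <- "1"
  if (!is.null(fixed)) {
    safe <- make.names(terms, unique = TRUE)
    for (j in seq_along(terms)) df[[safe[j]]] <- fixed[, j]
    rhs <- paste(safe, collapse = " + ")
  }
  fml <- stats::as.formula(paste0(".y ~ ", rhs,
                                  " + (1 | .subject) + (1 | .item)"))
  fm <- suppressMessages(withCallingHandlers(
    lme4::lmer(fml, data = df, REML = (method == "REML"),
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular = "ignore")),
    warning = function(w) invokeRestart("muffleWarning")))
  lmm_fit_from_merMod(fm, terms, method, n)
}

lmm_fit_from_merMod <- function(fm, terms, method, n) {
  est <- lme4::fixef(fm)
  se <- sqrt(diag(as.matrix(stats::vcov(fm))))
  names(se) <- names(est)
  if (!is.null(terms) && length(terms)) {
    # restore user-supplied term names (lmer saw syntactic aliases)
    names(est) <- names(se) <- c("(Intercept)", terms)
  }
  vcs <- lme4::VarCorr(fm)
  vc <- c(subject = as.numeric(vcs$.subject), item = as.numeric(vcs$.item),
          residual = attr(vcs, "sc")^2)
  conv <- is.null(fm@optinfo$conv$lme4$code) &&
    length(fm@optinfo$warnings) == 0
  structure(list(coefficients = est, se = se, t = est / se, vc = vc,
                 logLik = as.numeric(stats::logLik(fm)), method = method,
                 converged = conv, degenerate = FALSE, n = n, model = fm),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit> %s, n = %d, logLik = %.3f%s\n", x$method, x$n,
              if (is.na(x$logLik)) NA else x$logLik,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(data.frame(estimate = x$coefficients, se = x$se, t = x$t))
  cat(sprintf("variances: subject %.4g, item %.4g, residual %.4g\n",
              x$vc[1], x$vc[2], x$vc[3]))
  invisible(x)
}

#' Serialize an `lmm_fit` to JSON
#' @param fit an `lmm_fit`.
#' @param path file path.
#' @export
write_lmm_fit <- function(fit, path) {
  jsonlite::write_json(
    list(coefficients = as.list(fit$coefficients), se = as.list(fit$se),
         t = as.list(fit$t), vc = as.list(fit$vc), logLik = fit$logLik,
         method = fit$method, converged = fit$converged, n = fit$n),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Likelihood-ratio test of nested fixed-effect structures
#'
#' Both models are fitted by maximum likelihood (fixed-effects comparison),
#' and `chi_sq = 2 * (logLik_full - logLik_reduced)`, clipped at zero, is
#' referred to a chi-squared distribution with df equal to the difference in
#' fixed-term count.
#'
#' @param response numeric vector.
#' @param fixed_reduced,fixed_full named design matrices; the reduced terms
#'   must be a subset of the full terms.
#' @param subject,item grouping vectors.
#' @return list with `chi_sq`, `df`, `p`, and both `lmm_fit`s.
#' @export
lrt_nested <- function(response, fixed_reduced, fixed_full, subject, item) {
  red <- colnames(fixed_reduced)
  full <- colnames(fixed_full)
  if (is.null(fixed_reduced)) red <- character(0)
  if (!all(red %in% full))
    stop("models are not nested: reduced terms must be a subset of full terms")
  if (length(red) >= length(full))
    stop("full model must add at least one term")
  f_red <- fit_lmm(response, fixed_reduced, subject, item, method = "ML")
  added <- setdiff(full, red)
  zero_added <- added[apply(fixed_full[, added, drop = FALSE], 2,
                            function(v) all(v == 0))]
  keep_cols <- setdiff(full, zero_added)
  if (length(keep_cols) > length(red)) {
    f_full <- fit_lmm(response, fixed_full[, keep_cols, drop = FALSE],
                      subject, item, method = "ML")
    chi_sq <- max(0, 2 * (f_full$logLik - f_red$logLik))
  } else {
    # every added column is identically zero: the models coincide
    f_full <- f_red
    chi_sq <- 0
  }
  df <- length(full) - length(red)
  list(chi_sq = chi_sq, df = df,
       p = stats::pchisq(chi_sq, df, lower.tail = FALSE),
       fit_reduced = f_red, fit_full = f_full)
}

# 0/1 indicator of the second level of a two-level factor; errors otherwise.
binary_indicator <- function(x, term) {
  f <- factor(x)
  if (nlevels(f) != 2)
    stop(sprintf("term '%s' must take exactly 2 observed levels", term))
  as.numeric(f == levels(f)[2])
}

# n x P matrix of permuted binary labels. "within_subject" permutes each
# subject's labels among that subject's own trials (preserving per-subject
# related/unrelated counts); "free" permutes across the whole table.
permute_labels <- function(x01, subject, n_perm, scheme) {
  n <- length(x01)
  out <- matrix(0, n, n_perm)
  if (scheme == "free") {
    for (p in seq_len(n_perm)) out[, p] <- x01[sample.int(n)]
  } else {
    rows <- split(seq_len(n), subject)
    for (r in rows) {
      lab <- x01[r]
      for (p in seq_len(n_perm)) out[r, p] <- lab[sample.int(length(r))]
    }
  }
  out
}

#' Monte-Carlo permutation p-value for a two-level fixed effect
#'
#' Refits the crossed random-intercept model under random relabelings of the
#' term (by default within subject, preserving each subject's label counts)
#' and returns the add-one permutation p-value
#' `(1 + #\{|t_perm| >= |t_obs|\}) / (1 + n_iter)`. Permuted-label t-values
#' are computed by generalized least squares with the observed fit's variance
#' components held fixed, under which the observed t equals the mixed-model
#' t exactly.
#'
#' @param trials trial table.
#' @param term name of a two-level factor column (default `"prime_type"`).
#' @param response name of the response column (default `"rt_ms"`).
#' @param n_iter number of permutations (default 10000).
#' @param seed integer seed.
#' @param scheme `"within_subject"` (default) or `"free"`.
#' @return list with `p`, `t_obs`, `n_iter`, and the observed `lmm_fit`.
#' @export
mc_pvalue_fixed_effect <- function(trials, term = "prime_type",
                                   response = "rt_ms", n_iter = 10000,
                                   seed = 1L,
                                   scheme = c("within_subject", "free")) {
  scheme <- match.arg(scheme)
  stopifnot(n_iter >= 1)
  keep <- !is.na(trials[[response]])
  trials <- trials[keep, ]
  x01 <- binary_indicator(trials[[term]], term)
  y <- trials[[response]]
  fit <- fit_lmm(y, matrix(x01, dimnames = list(NULL, term)),
                 trials$subject_id, trials$item_id, method = "REML")
  eng <- gls_engine(trials$subject_id, trials$item_id, fit$vc)
  t_obs <- gls_binary_t(eng, matrix(x01, ncol = 1), y)
  t_perm <- with_seed(seed, {
    Xp <- permute_labels(x01, trials$subject_id, n_iter, scheme)
    gls_binary_t(eng, Xp, y)
  })
  p <- (1 + sum(abs(t_perm) >= abs(t_obs) - 1e-12)) / (1 + n_iter)
  list(p = p, t_obs = t_obs, n_iter = n_iter, fit = fit)
}
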