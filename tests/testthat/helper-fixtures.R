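# Shared fixture builders and independent oracles, all generated in code.

# One-condition counterbalanced design: each subject sees every item once,
# half related / half unrelated, with the assignment flipped between the two
# subject groups (so items appear under both prime types across subjects).
cb_design <- function(n_subj = 16, n_item = 50) {
  d <- expand.grid(item_id = factor(sprintf("i%03d", seq_len(n_item))),
                   subject_id = factor(sprintf("s%02d", seq_len(n_subj))))
  rel_a <- rep(c(TRUE, FALSE), length.out = n_item)
  ver_a <- rep(c(TRUE, FALSE), length.out = n_subj)
  d$prime_type <- ifelse(ver_a[as.integer(d$subject_id)] ==
                           rel_a[as.integer(d$item_id)],
                         "related", "unrelated")
  d$condition <- "test"
  d[, c("subject_id", "item_id", "condition", "prime_type")]
}

# Epochs for a design: AR(1) trial noise plus subject/item random shifts and
# an optional effect added to related trials over an index window.
make_epochs <- function(design, nt = 51, noise_sd = 1, rho = 0.95,
                        subject_sd = 0.3, item_sd = 0.3,
                        effect = 0, effect_idx = NULL) {
  n <- nrow(design)
  Y <- megpriming:::ar1_noise(n, nt, noise_sd, rho) +
    rnorm(nlevels(design$subject_id), 0, subject_sd)[as.integer(design$subject_id)] +
    rnorm(nlevels(design$item_id), 0, item_sd)[as.integer(design$item_id)]
  if (effect != 0 && !is.null(effect_idx)) {
    rel <- design$prime_type == "related"
    Y[rel, effect_idx] <- Y[rel, effect_idx] + effect
  }
  epoch_set(Y, seq(0, nt - 1), trial_index = seq_len(n))
}

# Brute-force cluster enumeration: walks the series index by index,
# independent of the rle-based implementation.
brute_clusters <- function(v, thr, two_sided = TRUE) {
  out <- list()
  cur <- NULL
  sgn_of <- function(x) {
    if (x > thr) 1L else if (two_sided && x < -thr) -1L else 0L
  }
  for (i in seq_along(v)) {
    s <- sgn_of(v[i])
    if (!is.null(cur) && (s == 0L || s != cur$sign)) {
      out[[length(out) + 1]] <- cur
      cur <- NULL
    }
    if (s != 0L) {
      if (is.null(cur)) cur <- list(start = i, end = i, sign = s, mass = v[i])
      else { cur$end <- i; cur$mass <- cur$mass + v[i] }
    }
  }
  if (!is.null(cur)) out[[length(out) + 1]] <- cur
  out
}

brute_max_mass <- function(v, thr, two_sided = TRUE) {
  cl <- brute_clusters(v, thr, two_sided)
  if (!length(cl)) 0 else max(vapply(cl, function(c) abs(c$mass), numeric(1)))
}

# Dense-matrix GLS oracle: builds the full n x n covariance
# V = vs Zs Zs' + vi Zi Zi' + ve I and computes the slope t for X = [1, x]
# by explicit solve(). Independent of the Woodbury machinery.
dense_gls_t <- function(subject, item, vc, x, y) {
  Zs <- stats::model.matrix(~ 0 + factor(subject))
  Zi <- stats::model.matrix(~ 0 + factor(item))
  V <- vc[1] * tcrossprod(Zs) + vc[2] * tcrossprod(Zi) +
    vc[3] * diag(length(y))
  X <- cbind(1, x)
  XtVi <- t(solve(V, X))
  A <- XtVi %*% X
  beta <- solve(A, XtVi %*% y)
  se <- sqrt(diag(solve(A)))
  (beta / se)[2]
}

# All distinct within-subject relabelings of a binary label vector
# (per-subject choose(n_s, k_s) combinations), as an n x P matrix.
enumerate_within_subject <- function(x01, subject) {
  rows <- split(seq_along(x01), subject)
  per_subj <- lapply(rows, function(r) {
    k <- sum(x01[r])
    combs <- utils::combn(length(r), k)
    apply(combs, 2, function(ix) {
      v <- numeric(length(r)); v[ix] <- 1; v
    })
  })
  grids <- lapply(per_subj, function(m) seq_len(ncol(m)))
  combos <- expand.grid(grids)
  out <- matrix(0, length(x01), nrow(combos))
  for (p in seq_len(nrow(combos))) {
    for (s in seq_along(rows)) {
      out[rows[[s]], p] <- per_subj[[s]][, combos[p, s]]
    }
  }
  out
}
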