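# Generalized least squares under the crossed random-intercept covariance
# V = sigma_s^2 Zs Zs' + sigma_i^2 Zi Zi' + sigma_e^2 I, with the variance
# components held fixed. Quadratic forms u' V^{-1} w are computed through the
# Woodbury identity, so each permuted-label statistic costs O(n + q^2) rather
# than O(n^3). This is the score-approximation fast path of the permutation
# machinery; with the same components, the resulting t equals the mixed-model
# t exactly, and the Wald interaction chi^2 equals the likelihood-ratio chi^2
# that a fixed-V Gaussian model would give.

# subject, item: factors (or vectors); vc: c(subject, item, residual) variances.
gls_engine <- function(subject, item, vc) {
  n <- length(subject)
  sig2e <- max(vc[3], 1e-12)
  blocks <- list()
  if (vc[1] > 1e-10 * sig2e)
    blocks$subject <- list(f = factor(subject), var = vc[1])
  if (vc[2] > 1e-10 * sig2e)
    blocks$item <- list(f = factor(item), var = vc[2])
  if (length(blocks) == 0) {
    return(list(n = n, sig2e = sig2e, q = 0L, Zt = NULL, Minv = NULL))
  }
  Zt_list <- lapply(blocks, function(b)
    Matrix::t(Matrix::sparse.model.matrix(~ 0 + b$f)))
  Zt <- do.call(rbind, Zt_list)
  ridge <- unlist(lapply(blocks, function(b)
    rep(sig2e / b$var, nlevels(b$f))))
  M <- as.matrix(Matrix::tcrossprod(Zt))
  diag(M) <- diag(M) + ridge
  list(n = n, sig2e = sig2e, q = nrow(Zt), Zt = Zt,
       Minv = chol2inv(chol(M)))
}

# a x b matrix of u' V^{-1} w for columns of U (n x a) and W (n x b).
gls_cross <- function(eng, U, W) {
  U <- as.matrix(U); W <- as.matrix(W)
  raw <- crossprod(U, W)
  if (eng$q == 0) return(raw / eng$sig2e)
  ZtU <- as.matrix(eng$Zt %*% U)
  ZtW <- as.matrix(eng$Zt %*% W)
  (raw - crossprod(ZtU, eng$Minv %*% ZtW)) / eng$sig2e
}

# t statistics for the slope of a binary regressor under X = [1, x], one per
# column of Xp (n x P matrix of 0/1 labels), sharing the response y.
gls_binary_t <- function(eng, Xp, y) {
  Xp <- as.matrix(Xp)
  n <- eng$n
  one <- rep(1, n)
  if (eng$q > 0) {
    ZtX <- as.matrix(eng$Zt %*% Xp)
    Zt1 <- as.numeric(eng$Zt %*% one)
    Zty <- as.numeric(eng$Zt %*% y)
    MZt1 <- as.numeric(eng$Minv %*% Zt1)
    MZty <- as.numeric(eng$Minv %*% Zty)
    MZtX <- eng$Minv %*% ZtX
    a11 <- (n - sum(Zt1 * MZt1)) / eng$sig2e
    a1y <- (sum(y) - sum(Zt1 * MZty)) / eng$sig2e
    a1x <- (colSums(Xp) - colSums(ZtX * MZt1)) / eng$sig2e
    axx <- (colSums(Xp) - colSums(ZtX * MZtX)) / eng$sig2e
    axy <- (as.numeric(crossprod(Xp, y)) - colSums(ZtX * MZty)) / eng$sig2e
  } else {
    a11 <- n / eng$sig2e
    a1y <- sum(y) / eng$sig2e
    a1x <- colSums(Xp) / eng$sig2e
    axx <- colSums(Xp) / eng$sig2e  # x binary: x'x = sum(x)
    axy <- as.numeric(crossprod(Xp, y)) / eng$sig2e
  }
  det <- a11 * axx - a1x^2
  (a11 * axy - a1x * a1y) / sqrt(pmax(det * a11, 1e-300))
}

# Precomputed machinery shared across timepoints: the random-effect incidence
# matrix Z and all label-dependent cross-products are built once; only the
# ridge (variance-component) part of M changes per timepoint.
gls_prepare <- function(subject, item, Xp, b = NULL) {
  Zts <- Matrix::t(Matrix::sparse.model.matrix(~ 0 + factor(subject)))
  Zti <- Matrix::t(Matrix::sparse.model.matrix(~ 0 + factor(item)))
  Zt <- rbind(Zts, Zti)
  Xp <- as.matrix(Xp)
  prep <- list(Zt = Zt, ZtZ = as.matrix(Matrix::tcrossprod(Zt)),
               group = rep(1:2, c(nrow(Zts), nrow(Zti))),
               n = ncol(Zt), P = ncol(Xp), Xp = Xp,
               Zt1 = Matrix::rowSums(Zt),
               ZtX = as.matrix(Zt %*% Xp), colX = colSums(Xp))
  if (!is.null(b)) {
    Xb <- Xp * b
    prep$b <- b
    prep$Xb <- Xb
    prep$ZtXb <- as.matrix(Zt %*% Xb)
    prep$Ztb <- as.numeric(Zt %*% b)
    prep$colXb <- colSums(Xb)
    prep$colXb2 <- colSums(Xb^2)
  }
  prep
}

gls_minv <- function(prep, vc) {
  sig2e <- max(vc[3], 1e-12)
  ridge <- sig2e / pmax(c(vc[1], vc[2])[prep$group], 1e-8 * sig2e)
  M <- prep$ZtZ
  diag(M) <- diag(M) + ridge
  list(Minv = chol2inv(chol(M)), sig2e = sig2e)
}

# Slope t-values for X = [1, x], all label columns of prep$Xp at once, at one
# timepoint's variance components. xty, if given, is crossprod(Xp, y).
gls_t_at_vc <- function(prep, vc, y, xty = NULL) {
  mv <- gls_minv(prep, vc)
  Minv <- mv$Minv; sig2e <- mv$sig2e
  if (is.null(xty)) xty <- as.numeric(crossprod(prep$Xp, y))
  Zty <- as.numeric(prep$Zt %*% y)
  MZt1 <- as.numeric(Minv %*% prep$Zt1)
  MZty <- as.numeric(Minv %*% Zty)
  MZtX <- Minv %*% prep$ZtX
  a11 <- (prep$n - sum(prep$Zt1 * MZt1)) / sig2e
  a1y <- (sum(y) - sum(prep$Zt1 * MZty)) / sig2e
  a1x <- (prep$colX - colSums(prep$ZtX * MZt1)) / sig2e
  axx <- (prep$colX - colSums(prep$ZtX * MZtX)) / sig2e
  axy <- (xty - colSums(prep$ZtX * MZty)) / sig2e
  det <- a11 * axx - a1x^2
  (a11 * axy - a1x * a1y) / sqrt(pmax(det * a11, 1e-300))
}

# Interaction Wald chi^2 for X = [1, b, x, x*b], all label columns at once,
# at one timepoint's variance components.
gls_chisq_at_vc <- function(prep, vc, y) {
  mv <- gls_minv(prep, vc)
  Minv <- mv$Minv; sig2e <- mv$sig2e
  Zty <- as.numeric(prep$Zt %*% y)
  MZt1 <- as.numeric(Minv %*% prep$Zt1)
  MZtb <- as.numeric(Minv %*% prep$Ztb)
  MZty <- as.numeric(Minv %*% Zty)
  MZtX <- Minv %*% prep$ZtX
  MZtXb <- Minv %*% prep$ZtXb
  a11 <- (prep$n - sum(prep$Zt1 * MZt1)) / sig2e
  a1b <- (sum(prep$b) - sum(prep$Zt1 * MZtb)) / sig2e
  abb <- (sum(prep$b^2) - sum(prep$Ztb * MZtb)) / sig2e
  a1y <- (sum(y) - sum(prep$Zt1 * MZty)) / sig2e
  aby <- (sum(prep$b * y) - sum(prep$Ztb * MZty)) / sig2e
  a1x <- (prep$colX - colSums(prep$ZtX * MZt1)) / sig2e
  a1xb <- (prep$colXb - colSums(prep$ZtXb * MZt1)) / sig2e
  abx <- (as.numeric(crossprod(prep$Xp, prep$b)) -
            colSums(prep$ZtX * MZtb)) / sig2e
  abxb <- (as.numeric(crossprod(prep$Xb, prep$b)) -
             colSums(prep$ZtXb * MZtb)) / sig2e
  axx <- (prep$colX - colSums(prep$ZtX * MZtX)) / sig2e
  axxb <- (prep$colXb - colSums(prep$ZtX * MZtXb)) / sig2e
  axbxb <- (prep$colXb2 - colSums(prep$ZtXb * MZtXb)) / sig2e
  axy <- (as.numeric(crossprod(prep$Xp, y)) -
            colSums(prep$ZtX * MZty)) / sig2e
  axby <- (as.numeric(crossprod(prep$Xb, y)) -
             colSums(prep$ZtXb * MZty)) / sig2e
  chisq <- numeric(prep$P)
  for (p in seq_len(prep$P)) {
    A <- matrix(c(a11,     a1b,     a1x[p],  a1xb[p],
                  a1b,     abb,     abx[p],  abxb[p],
                  a1x[p],  abx[p],  axx[p],  axxb[p],
                  a1xb[p], abxb[p], axxb[p], axbxb[p]), 4, 4)
    rhs <- c(a1y, aby, axy[p], axby[p])
    Ainv <- tryCatch(solve(A), error = function(e) NULL)
    if (is.null(Ainv)) { chisq[p] <- 0; next }
    beta <- Ainv %*% rhs
    chisq[p] <- max(0, beta[4]^2 / Ainv[4, 4])
  }
  chisq
}

# Wald chi^2 for the interaction slope in X = [1, b, x, x*b], one per column
# of Xp; b is a fixed numeric moderator. With V fixed this equals the
# likelihood-ratio chi^2 of adding x*b.
gls_interaction_chisq <- function(eng, Xp, b, y) {
  Xp <- as.matrix(Xp)
  n <- eng$n
  P <- ncol(Xp)
  Fmat <- cbind(1, b)
  Xb <- Xp * b
  C_FF <- gls_cross(eng, Fmat, Fmat)
  C_Fy <- gls_cross(eng, Fmat, y)
  C_FX <- gls_cross(eng, Fmat, Xp)    # 2 x P
  C_FXb <- gls_cross(eng, Fmat, Xb)   # 2 x P
  if (eng$q > 0) {
    ZtX <- as.matrix(eng$Zt %*% Xp)
    ZtXb <- as.matrix(eng$Zt %*% Xb)
    Zty <- as.numeric(eng$Zt %*% y)
    MZty <- as.numeric(eng$Minv %*% Zty)
    MZtX <- eng$Minv %*% ZtX
    MZtXb <- eng$Minv %*% ZtXb
    a_xx <- (colSums(Xp) - colSums(ZtX * MZtX)) / eng$sig2e
    a_xxb <- (colSums(Xb) - colSums(ZtX * MZtXb)) / eng$sig2e  # x*(x*b) = x*b
    a_xbxb <- (colSums(Xb^2) - colSums(ZtXb * MZtXb)) / eng$sig2e
    a_xy <- (as.numeric(crossprod(Xp, y)) - colSums(ZtX * MZty)) / eng$sig2e
    a_xby <- (as.numeric(crossprod(Xb, y)) - colSums(ZtXb * MZty)) / eng$sig2e
  } else {
    a_xx <- colSums(Xp) / eng$sig2e
    a_xxb <- colSums(Xb) / eng$sig2e
    a_xbxb <- colSums(Xb^2) / eng$sig2e
    a_xy <- as.numeric(crossprod(Xp, y)) / eng$sig2e
    a_xby <- as.numeric(crossprod(Xb, y)) / eng$sig2e
  }
  chisq <- numeric(P)
  for (p in seq_len(P)) {
    A <- matrix(0, 4, 4)
    A[1:2, 1:2] <- C_FF
    A[1:2, 3] <- C_FX[, p];  A[3, 1:2] <- C_FX[, p]
    A[1:2, 4] <- C_FXb[, p]; A[4, 1:2] <- C_FXb[, p]
    A[3, 3] <- a_xx[p]
    A[3, 4] <- a_xxb[p]; A[4, 3] <- a_xxb[p]
    A[4, 4] <- a_xbxb[p]
    rhs <- c(C_Fy, a_xy[p], a_xby[p])
    Ainv <- tryCatch(solve(A), error = function(e) NULL)
    if (is.null(Ainv)) { chisq[p] <- 0; next }
    beta <- Ainv %*% rhs
    chisq[p] <- max(0, beta[4]^2 / Ainv[4, 4])
  }
  chisq
}
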