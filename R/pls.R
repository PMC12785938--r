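# Internal PLS1 engine (SIMPLS, de Jong 1993) used by the PLSR baseline and
# by CARS. Returns coefficient vectors for every component count up to ncomp
# in one pass, which makes cross-validation over a latent-variable range
# cheap.

# X: n x p, y: length n. Returns list with coefs (p x ncomp matrix, column a
# = regression vector using a components, on the original scale), xmean,
# ymean, ncomp (possibly reduced if X runs out of rank).
.pls_fit <- function(X, y, ncomp) {
  n <- nrow(X); p <- ncol(X)
  ncomp <- min(ncomp, n - 1L, p)
  if (ncomp < 1L) stop("PLS needs at least 1 feasible component")
  xmean <- colMeans(X); ymean <- mean(y)
  Xc <- sweep(X, 2L, xmean)
  yc <- y - ymean
  S <- crossprod(Xc, yc)                    # p x 1
  R <- matrix(0, p, ncomp)
  V <- matrix(0, p, ncomp)
  Q <- numeric(ncomp)
  a_used <- 0L
  for (a in seq_len(ncomp)) {
    r <- S
    tt <- Xc %*% r
    tt <- tt - mean(tt)
    nt <- sqrt(sum(tt^2))
    if (nt < 1e-12) break                   # residual rank exhausted
    tt <- tt / nt; r <- r / nt
    p_load <- crossprod(Xc, tt)
    Q[a] <- sum(yc * tt)
    v <- p_load
    if (a > 1L) {
      Vp <- V[, seq_len(a - 1L), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, p_load)
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) break
    v <- v / nv
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r; V[, a] <- v
    a_used <- a
  }
  if (a_used == 0L) stop("degenerate PLS fit: X has no usable variance")
  coefs <- matrix(0, p, a_used)
  for (a in seq_len(a_used))
    coefs[, a] <- R[, seq_len(a), drop = FALSE] %*% Q[seq_len(a)]
  list(coefs = coefs, xmean = xmean, ymean = ymean, ncomp = a_used)
}

# Predict with a .pls_fit result; `a` = number of components (default: all).
.pls_predict <- function(fit, X, a = fit$ncomp) {
  a <- min(a, fit$ncomp)
  unname(drop(sweep(X, 2L, fit$xmean) %*% fit$coefs[, a] + fit$ymean))
}

# Seeded contiguous-block fold assignment after a shuffle; shared by every CV
# routine so fold structure is comparable across models.
.make_folds <- function(n, folds, seed) {
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(n)
  split(idx, cut(seq_len(n), breaks = folds, labels = FALSE))
}

# Pooled RMSECV of a PLS model with `a` components on (X, y).
.pls_rmsecv <- function(X, y, a, folds = 5L, seed = 1L) {
  fl <- .make_folds(nrow(X), folds, seed)
  se <- 0
  for (f in fl) {
    fit <- .pls_fit(X[-f, , drop = FALSE], y[-f], a)
    se <- se + sum((y[f] - .pls_predict(fit, X[f, , drop = FALSE]))^2)
  }
  sqrt(se / nrow(X))
}
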