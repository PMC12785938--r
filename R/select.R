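# Wavelength selection: competitive adaptive reweighted sampling (CARS) and
# the successive projections algorithm (SPA). Both return a VariableSubset
# scored by calibration RMSECV and are fully reproducible given a seed.

#' Exponentially decreasing retention fraction used by CARS
#'
#' `r_i = a * exp(-k * i)` with `a`, `k` fixed by the boundary conditions
#' `r_1 = 1` (all variables kept in the first run) and `r_N = 2/p` (only two
#' kept in the last).
#'
#' @param run_index run number(s) `i`, in `1..total_runs` (vectorised).
#' @param total_runs number of Monte-Carlo runs `N`.
#' @param p number of variables (> 2).
#' @return retained fraction(s) in `(0, 1]`.
#' @export
edf_ratio <- function(run_index, total_runs, p) {
  if (p <= 2) stop("p must be > 2")
  if (any(run_index < 1 | run_index > total_runs))
    stop("run_index must lie in [1, total_runs]")
  a <- (p / 2)^(1 / (total_runs - 1))
  k <- log(p / 2) / (total_runs - 1)
  a * exp(-k * run_index)
}

.variable_subset <- function(indices, provenance, score) {
  indices <- sort(unique(as.integer(indices)))
  if (!length(indices)) stop("variable subset must be non-empty")
  structure(list(indices = indices, provenance = provenance, score = score),
            class = "VariableSubset")
}

#' @export
print.VariableSubset <- function(x, ...) {
  cat(sprintf("VariableSubset [%s]: %d variables, RMSECV = %.4g\n",
              x$provenance, length(x$indices), x$score))
  invisible(x)
}

.autoscale <- function(X) {
  mu <- colMeans(X); sg <- apply(X, 2L, sd); sg[sg == 0] <- 1
  sweep(sweep(X, 2L, mu), 2L, sg, "/")
}

#' CARS wavelength selection
#'
#' Per Monte-Carlo run: fit PLS on a random 80% row subsample restricted to
#' the currently retained variables, weight variables by their normalised
#' absolute regression coefficients (on autoscaled data), enforce the
#' exponentially decreasing retention count [edf_ratio()], then adaptively
#' resample among the enforced set with weight-proportional probabilities.
#' Each run's subset is scored by 5-fold PLS RMSECV on the full calibration
#' set; the subset with minimal RMSECV wins.
#'
#' @param calibration a `SpectraSet` (already preprocessed as desired).
#' @param mc_runs number of Monte-Carlo runs (default 50).
#' @param folds CV folds for the per-run RMSECV.
#' @param seed RNG seed; the whole selection is deterministic given it.
#' @param sample_frac row fraction per Monte-Carlo subsample.
#' @param ncomp_max cap on PLS components.
#' @return a `VariableSubset` with provenance `"cars"`; attribute `runs` holds
#'   the per-run EDF-enforced counts, retained counts and RMSECV values.
#' @export
cars_select <- function(calibration, mc_runs = 50L, folds = 5L, seed = 1L,
                        sample_frac = 0.8, ncomp_max = 10L) {
  X <- .as_matrix(calibration)
  y <- calibration$target
  n <- nrow(X); p <- ncol(X)
  if (n < folds) stop("calibration needs at least `folds` samples")
  if (p < 3L) stop("CARS needs at least 3 variables")
  set.seed(seed)
  Xs <- .autoscale(X)
  retained <- seq_len(p)
  runs <- data.frame(run = seq_len(mc_runs), edf_count = NA_integer_,
                     n_retained = NA_integer_, rmsecv = NA_real_)
  subsets <- vector("list", mc_runs)
  m <- max(2L, round(sample_frac * n))
  for (i in seq_len(mc_runs)) {
    rows <- sample.int(n, m)
    fit <- .pls_fit(Xs[rows, retained, drop = FALSE], y[rows],
                    min(ncomp_max, length(retained), m - 1L))
    b <- abs(fit$coefs[, fit$ncomp])
    if (sum(b) == 0) stop("degenerate PLS fit in CARS run ", i)
    w <- b / sum(b)
    keep_n <- min(max(2L, ceiling(edf_ratio(i, mc_runs, p) * p)),
                  length(retained))
    forced <- retained[order(w, decreasing = TRUE)[seq_len(keep_n)]]
    wf <- w[match(forced, retained)]
    # adaptive reweighted sampling: keep the variables that survive a
    # weight-proportional bootstrap among the enforced set
    drawn <- unique(sample(forced, size = keep_n, replace = TRUE,
                           prob = wf / sum(wf)))
    if (length(drawn) < 2L)
      drawn <- unique(c(drawn, forced[order(wf, decreasing = TRUE)][1:2]))
    retained <- sort(drawn)
    runs$edf_count[i] <- keep_n
    runs$n_retained[i] <- length(retained)
    runs$rmsecv[i] <- .pls_rmsecv(Xs[, retained, drop = FALSE], y,
                                  min(ncomp_max, length(retained), n - 1L),
                                  folds = folds, seed = seed)
    subsets[[i]] <- retained
  }
  best <- which.min(runs$rmsecv)
  out <- .variable_subset(subsets[[best]], "cars", runs$rmsecv[best])
  attr(out, "runs") <- runs
  out
}

# ---- SPA -------------------------------------------------------------------

# Build one SPA chain: starting from column `start`, repeatedly add the
# column with the largest Euclidean norm after orthogonal projection onto the
# complement of the span of the selected columns. Stops early when all
# projected norms fall below `tol` (rank exhausted).
.spa_chain <- function(X, start, kmax, tol = 1e-10) {
  p <- ncol(X)
  chain <- start
  P <- X
  v <- P[, start]
  for (step in seq_len(min(kmax, p) - 1L)) {
    nv2 <- sum(v^2)
    if (nv2 < tol) break
    P <- P - (v %*% crossprod(v, P)) / nv2     # project out the last pick
    norms <- colSums(P^2)
    norms[chain] <- -Inf
    j <- which.max(norms)
    if (norms[j] < tol) break
    chain <- c(chain, j)
    v <- P[, j]
  }
  chain
}

# 5-fold RMSECV of ordinary least squares (with intercept) on X[, sel].
.mlr_rmsecv <- function(X, y, folds = 5L, seed = 1L) {
  fl <- .make_folds(nrow(X), folds, seed)
  se <- 0
  for (f in fl) {
    Xtr <- cbind(1, X[-f, , drop = FALSE])
    beta <- qr.coef(qr(Xtr), y[-f])
    beta[is.na(beta)] <- 0
    se <- se + sum((y[f] - cbind(1, X[f, , drop = FALSE]) %*% beta)^2)
  }
  sqrt(se / nrow(X))
}

#' SPA wavelength selection
#'
#' For every candidate starting column, a chain of minimally collinear
#' variables is grown by successive orthogonal projections; every prefix of
#' length `min_vars..max_vars` is scored by 5-fold RMSECV of a multiple
#' linear regression, and the best (start, length) pair wins (ties: fewer
#' variables, then lower start index).
#'
#' @param calibration a `SpectraSet` (already preprocessed as desired).
#' @param min_vars,max_vars chain-length bounds; `max_vars` must not exceed
#'   `min(n - 1, p)`.
#' @param folds CV folds for scoring.
#' @param seed fold-shuffle seed.
#' @param starts candidate start columns (default: all).
#' @return a `VariableSubset` with provenance `"spa"`.
#' @export
spa_select <- function(calibration, min_vars = 5L, max_vars = 30L,
                       folds = 5L, seed = 1L, starts = NULL) {
  X <- .as_matrix(calibration)
  y <- calibration$target
  n <- nrow(X); p <- ncol(X)
  max_vars <- min(max_vars, n - 1L, p)
  if (!(min_vars >= 1L && min_vars <= max_vars))
    stop("need 1 <= min_vars <= max_vars <= min(n - 1, p)")
  if (is.null(starts)) starts <- seq_len(p)
  Xc <- sweep(X, 2L, colMeans(X))
  best <- list(score = Inf, sel = NULL)
  for (s in starts) {
    chain <- .spa_chain(Xc, s, max_vars)
    for (k in seq.int(min_vars, max_vars)) {
      if (k > length(chain)) break
      sel <- chain[seq_len(k)]
      sc <- .mlr_rmsecv(X[, sel, drop = FALSE], y, folds, seed)
      if (sc < best$score - 1e-15) best <- list(score = sc, sel = sel)
    }
  }
  if (is.null(best$sel)) stop("SPA found no feasible subset")
  .variable_subset(best$sel, "spa", best$score)
}
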