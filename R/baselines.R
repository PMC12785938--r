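# Classical calibration baselines: PLSR with cross-validated latent-variable
# selection, and epsilon-SVR with an RBF kernel tuned by a two-step grid
# search. Both follow standard chemometrics protocols: 5-fold CV on the
# calibration set only.

#' Fit PLSR with cross-validated latent-variable selection
#'
#' Selects the number of latent variables (LVs) minimising 5-fold RMSECV over
#' `lv_range` (ties go to fewer LVs), then refits on all calibration rows.
#'
#' @param calibration a `SpectraSet` or list with `absorbance`/`target`.
#' @param lv_range integer vector of candidate LV counts (default 5:20).
#' @param folds number of CV folds.
#' @param seed seed for the fold shuffle.
#' @return object of class `PlsrModel` with fields `n_latent`,
#'   `rmsecv_curve` (named by LV count), and the fitted coefficients.
#' @export
fit_plsr_cv <- function(calibration, lv_range = 5:20, folds = 5L, seed = 1L) {
  X <- .as_matrix(calibration)
  y <- calibration$target
  n <- nrow(X); p <- ncol(X)
  lv_range <- sort(unique(as.integer(lv_range)))
  lv_max_feasible <- min(n - 1L, p)
  if (any(lv_range < 1L) || min(lv_range) > lv_max_feasible)
    stop("lv_range infeasible: must intersect [1, ", lv_max_feasible, "]")
  lv_range <- lv_range[lv_range <= lv_max_feasible]
  if (n <= folds) stop("need more samples than folds")
  fl <- .make_folds(n, folds, seed)
  sse <- setNames(numeric(length(lv_range)), lv_range)
  for (f in fl) {
    fit <- .pls_fit(X[-f, , drop = FALSE], y[-f], max(lv_range))
    for (i in seq_along(lv_range)) {
      pred <- .pls_predict(fit, X[f, , drop = FALSE], lv_range[i])
      sse[i] <- sse[i] + sum((y[f] - pred)^2)
    }
  }
  rmsecv <- sqrt(sse / n)
  best <- lv_range[which.min(rmsecv)]  # which.min: fewest LVs on ties
  fit <- .pls_fit(X, y, best)
  structure(list(n_latent = best, fit = fit, rmsecv_curve = rmsecv,
                 p = p), class = "PlsrModel")
}

#' @export
predict.PlsrModel <- function(object, newdata, ...) {
  X <- .as_matrix(newdata)
  if (ncol(X) != object$p)
    stop("newdata has ", ncol(X), " variables; model expects ", object$p)
  .pls_predict(object$fit, X, object$n_latent)
}

# ---- epsilon-SVR (RBF) -----------------------------------------------------

# Dual coordinate descent for epsilon-SVR with the bias absorbed into the
# kernel (K + 1), removing the equality constraint -- the same augmentation
# trick liblinear uses. beta_i = alpha_i - alpha_i^* in [-C, C]; each
# coordinate has the closed-form soft-threshold update. Deterministic.
.svr_solve <- function(K, y, C, eps = 0.1, tol = 1e-6, max_pass = 2000L) {
  drop(svr_cd_cpp(K + 1, y, C, eps, tol, max_pass))
}

.rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

# Fit one SVR on z-scored X (scaling is the caller's job).
.svr_fit <- function(X, y, C, gamma, eps = 0.1) {
  K <- .rbf_kernel(X, X, gamma)
  beta <- .svr_solve(K, y, C, eps)
  list(X = X, beta = beta, gamma = gamma, C = C, eps = eps)
}

.svr_predict <- function(fit, Xnew) {
  unname(drop((.rbf_kernel(Xnew, fit$X, fit$gamma) + 1) %*% fit$beta))
}

#' Fit RBF-kernel SVR with a two-step grid search
#'
#' Step 1 scores a coarse log-spaced `(C, gamma)` grid by 5-fold RMSECV; step
#' 2 refines with 5 log-spaced points per axis spanning one decade around the
#' coarse optimum, then refits at the best pair. Predictors are z-scored on
#' calibration statistics before the RBF kernel is applied.
#'
#' @param calibration a `SpectraSet`.
#' @param C_grid,gamma_grid coarse grids (defaults reach the customary optima
#'   C in 10^(-1..3), gamma in 10^(-4..0)).
#' @param folds CV folds.
#' @param seed fold-shuffle seed.
#' @param epsilon width of the insensitive tube.
#' @return object of class `SvrModel` with `C`, `gamma`, the support
#'   structure, and the CV score table.
#' @export
fit_svr_gridsearch <- function(calibration,
                               C_grid = 10^(-1:3),
                               gamma_grid = 10^(-4:0),
                               folds = 5L, seed = 1L, epsilon = 0.1) {
  X <- .as_matrix(calibration)
  y <- calibration$target
  if (!length(C_grid) || !length(gamma_grid)) stop("grids must be non-empty")
  mu <- colMeans(X); sg <- apply(X, 2L, sd); sg[sg == 0] <- 1
  Xs <- sweep(sweep(X, 2L, mu), 2L, sg, "/")
  fl <- .make_folds(nrow(Xs), folds, seed)

  score_grid <- function(Cs, gs) {
    tab <- expand.grid(C = Cs, gamma = gs)
    tab$rmsecv <- vapply(seq_len(nrow(tab)), function(k) {
      se <- 0
      for (f in fl) {
        fit <- .svr_fit(Xs[-f, , drop = FALSE], y[-f], tab$C[k],
                        tab$gamma[k], epsilon)
        se <- se + sum((y[f] - .svr_predict(fit, Xs[f, , drop = FALSE]))^2)
      }
      sqrt(se / nrow(Xs))
    }, numeric(1))
    tab
  }

  coarse <- score_grid(C_grid, gamma_grid)
  b <- coarse[which.min(coarse$rmsecv), ]
  refine_axis <- function(center) 10^seq(log10(center) - 0.5,
                                         log10(center) + 0.5, length.out = 5L)
  fine <- score_grid(refine_axis(b$C), refine_axis(b$gamma))
  bf <- fine[which.min(fine$rmsecv), ]
  best <- if (bf$rmsecv <= b$rmsecv) bf else b
  fit <- .svr_fit(Xs, y, best$C, best$gamma, epsilon)
  structure(list(C = best$C, gamma = best$gamma, epsilon = epsilon,
                 fit = fit, center = mu, scale = sg,
                 coarse = coarse, fine = fine, p = ncol(X)),
            class = "SvrModel")
}

#' @export
predict.SvrModel <- function(object, newdata, ...) {
  X <- .as_matrix(newdata)
  if (ncol(X) != object$p)
    stop("newdata has ", ncol(X), " variables; model expects ", object$p)
  Xs <- sweep(sweep(X, 2L, object$center), 2L, object$scale, "/")
  .svr_predict(object$fit, Xs)
}
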