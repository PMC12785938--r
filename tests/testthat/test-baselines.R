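# PLSR oracle: saturated PLS on full-rank data equals ordinary least squares.

make_lowrank <- function(n = 30L, p = 12L, r = 3L, seed = 4L, noise = 0) {
  set.seed(seed)
  S <- matrix(rnorm(n * r), n, r)
  L <- matrix(rnorm(r * p), r, p)
  X <- S %*% L
  beta <- rnorm(r)
  y_raw <- drop(S %*% beta) + rnorm(n, 0, noise)
  y <- (y_raw - min(y_raw)) / diff(range(y_raw))
  spectra_set(X - min(X), seq(1000, 1000 + p - 1), y, rep("a", n))
}

test_that("PLSR recovers exact low-rank structure and RMSECV plateaus", {
  d <- make_lowrank()
  m <- fit_plsr_cv(d, lv_range = 1:8, folds = 5L, seed = 1L)
  # RMSECV is tiny from LV = 3 onward (3-component data, no noise)
  curve <- m$rmsecv_curve
  expect_lt(min(curve[as.integer(names(curve)) >= 3]), 1e-8)
  expect_lte(m$n_latent, 8L)
  expect_equal(predict(m, d), d$target, tolerance = 1e-8)
})

test_that("saturated PLSR equals the least-squares fit on full-rank data", {
  set.seed(8)
  n <- 20L; p <- 6L
  X <- matrix(rnorm(n * p), n, p)
  y <- runif(n)
  d <- spectra_set(X - min(X), seq(1000, 1005), y, rep("a", n))
  fit <- incepspect:::.pls_fit(d$absorbance, y, p)
  yhat <- incepspect:::.pls_predict(fit, d$absorbance)
  ols <- lm.fit(cbind(1, d$absorbance), y)
  expect_equal(yhat, unname(drop(cbind(1, d$absorbance) %*% ols$coefficients)),
               tolerance = 1e-8)
  # 1 LV on rank-1 signal equals simple regression on the dominant direction
  v <- rnorm(p)
  t_score <- rnorm(n)
  X1 <- outer(t_score, v)
  y1 <- 0.3 + 0.5 * t_score
  fit1 <- incepspect:::.pls_fit(X1, y1, 1L)
  expect_equal(incepspect:::.pls_predict(fit1, X1), y1, tolerance = 1e-8)
})

test_that("fit_plsr_cv validates its LV range and default range is 5-20", {
  d <- make_lowrank()
  expect_error(fit_plsr_cv(d, lv_range = 50:60), "infeasible")
  expect_identical(formals(fit_plsr_cv)$lv_range, quote(5:20))
  # ties prefer fewer LVs: on noiseless data the curve is flat at ~0 from
  # rank onward, so selection must not pick more LVs than needed
  m <- fit_plsr_cv(d, lv_range = 3:8, seed = 1L)
  expect_equal(m$n_latent, 3L)
  expect_error(predict(m, tiny_set(p = 4L)), "variables")
})

test_that("SVR fits a smooth nonlinear function and the grid search works", {
  set.seed(11)
  n <- 60L
  x <- sort(runif(n, 0, 1))
  X <- cbind(x, x^2)
  y <- 0.5 + 0.3 * sin(2 * pi * x)
  y <- (y - min(y)) / diff(range(y))
  d <- spectra_set(X, c(1000, 1100), y, rep("a", n))
  # single-point grids return that pair
  m1 <- fit_svr_gridsearch(d, C_grid = 10, gamma_grid = 0.5, seed = 1L)
  expect_true(m1$C >= 10 / sqrt(10) && m1$C <= 10 * sqrt(10))  # refined near 10
  m <- fit_svr_gridsearch(d, seed = 1L)
  expect_gt(m$C, 0); expect_gt(m$gamma, 0)
  expect_lt(rmse(y, predict(m, d)), 0.12)      # fits within the eps tube scale
  # determinism
  m2 <- fit_svr_gridsearch(d, seed = 1L)
  expect_identical(coef <- m$fit$beta, m2$fit$beta)
  expect_identical(c(m$C, m$gamma), c(m2$C, m2$gamma))
  expect_error(predict(m, tiny_set(p = 5L)), "variables")
})

test_that("SVR dual solution satisfies KKT-style optimality on a toy problem", {
  # beta_i = 0 implies |residual| <= eps; |beta_i| = C implies |residual| >= eps
  set.seed(12)
  n <- 40L
  X <- matrix(runif(n * 2), n, 2)
  y <- 0.2 + 0.5 * X[, 1] - 0.3 * X[, 2] + rnorm(n, 0, 0.05)
  K <- incepspect:::.rbf_kernel(X, X, 1)
  C <- 10; eps <- 0.1
  beta <- incepspect:::.svr_solve(K, y, C, eps)
  f <- drop((K + 1) %*% beta)
  r <- y - f
  tol <- 1e-4
  expect_true(all(abs(r[beta == 0]) <= eps + tol))
  inside <- abs(beta) > tol & abs(beta) < C - tol
  expect_true(all(abs(abs(r[inside]) - eps) < tol))
})

test_that("constant targets produce constant predictions", {
  set.seed(13)
  X <- matrix(runif(30), 10, 3)
  d <- spectra_set(X, c(1000, 1100, 1200), rep(0.4, 10), rep("a", 10))
  m <- fit_svr_gridsearch(d, C_grid = 1, gamma_grid = 0.1, seed = 1L)
  p <- predict(m, d)
  # epsilon-SVR leaves up to eps of slack around a constant target
  expect_true(all(abs(p - 0.4) <= m$epsilon + 1e-6))
  expect_lt(diff(range(p)), 0.05)              # near-constant prediction
})
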