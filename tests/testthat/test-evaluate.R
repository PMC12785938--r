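test_that("r2, rmse and rpd follow their definitions", {
  y <- c(0, 1, 2)
  expect_equal(r2(y, y), 1)
  expect_equal(r2(y, rep(mean(y), 3)), 0)
  expect_equal(r2(y, c(0, 1, 1)), 0.5)
  expect_error(r2(c(1, 1), c(1, 2)), "constant")
  expect_error(r2(1:3, 1:2), "mismatch")

  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_equal(rmse(1, 0), 1)

  # rpd x rmse = sd(y_true), and the banding labels
  set.seed(31)
  for (i in 1:10) {
    yt <- runif(8); yp <- yt + rnorm(8, 0, 0.1)
    v <- rpd(yt, yp)
    expect_equal(as.numeric(v) * rmse(yt, yp), sd(yt), tolerance = 1e-10)
  }
  # shift predictions so rmse equals sd(y): RPD exactly 1, "poor"
  yt <- c(0.1, 0.4, 0.9, 0.3)
  yp <- yt + sd(yt)
  expect_equal(as.numeric(rpd(yt, yp)), 1)
  expect_equal(attr(rpd(yt, yp), "label"), "poor")
  expect_equal(rpd_label(2.7), "acceptable")
  expect_equal(rpd_label(3.0), "excellent")
  expect_equal(rpd_label(2.39), "poor")
  v0 <- rpd(yt, yt)
  expect_true(is.infinite(v0) && isTRUE(attr(v0, "zero_rmse")))
})

test_that("metrics are invariant to sample order", {
  set.seed(32)
  y <- runif(20); p <- y + rnorm(20, 0, 0.05)
  o <- sample(20)
  expect_equal(r2(y, p), r2(y[o], p[o]))
  expect_equal(rmse(y, p), rmse(y[o], p[o]))
})

test_that("rmsecv refits per fold, is seeded, and matches the mean-predictor scale", {
  d <- noiseless_series()
  plsr_fit <- function(cal) fit_plsr_cv(cal, lv_range = 1:3, seed = 1L)
  v1 <- rmsecv(plsr_fit, d, folds = 5L, seed = 1L)
  expect_lt(v1, 1e-6)                               # noiseless linear data
  expect_identical(v1, rmsecv(plsr_fit, d, folds = 5L, seed = 1L))
  # fold-wise mean predictor approximates sd(y) (direct computation); use a
  # full-size series so the finite-fold deviation is small
  dbig <- simulate_dataset(mixture_design(adulterants = "corn_flour"),
                           noise_model(seed = 4L), default_grid(30L))
  mean_fit <- function(cal) { m <- mean(cal$target); function(nd) rep(m, n_samples(nd)) }
  v2 <- rmsecv(mean_fit, dbig, folds = 5L, seed = 1L)
  expect_lt(abs(v2 - sd(dbig$target)) / sd(dbig$target), 0.10)
})

test_that("residual_table reports bias indicators", {
  d <- tiny_set(n = 8L, p = 4L, seed = 33L)
  rt <- residual_table(d$target, d)                 # perfect predictions
  expect_true(all(rt$residual == 0))
  rt2 <- residual_table(d$target + 0.1, d)          # constant over-prediction
  expect_equal(attr(rt2, "mean_residual"), 0.1, tolerance = 1e-12)
  # U-shaped residuals from a linear model on a quadratic response are
  # detectable through the rank correlation of |residual| vs target distance
  set.seed(34)
  x <- seq(0, 1, length.out = 40)
  y <- (x - 0.5)^2 * 2 + rnorm(40, 0, 0.005)
  y <- pmin(pmax(y, 0), 1)
  dq <- spectra_set(cbind(x, 1 - x), c(1000, 1100), y, rep("a", 40))
  lin <- lm(y ~ x)
  rtq <- residual_table(unname(fitted(lin)), dq)
  rc <- cor(abs(rtq$residual), abs(dq$target - median(dq$target)),
            method = "spearman")
  expect_gt(abs(rc), 0)
})

test_that("run_experiment executes the matrix, records failures, reruns identically", {
  d <- simulate_dataset(mixture_design(levels = seq(0, 1, 0.2),
                                       adulterants = c("corn_flour", "wheat_bran"),
                                       replicates_per_level = 3L),
                        noise_model(seed = 6L), default_grid(40L))
  cfg <- list(data = d, models = c("plsr", "incepspect_cbam"),
              strategies = "raw", scopes = c("combined", "corn_flour"),
              seeds = 1L, fraction = 0.8, compute_rmsecv = FALSE,
              plsr_args = list(lv_range = 1:5),
              net_args = list(branch_ch1 = 2L, branch_ch2 = 2L,
                              fc_units = 8L, batch_size = 8L,
                              max_epochs = 8L, patience = 8L))
  rep1 <- run_experiment(cfg)
  expect_equal(nrow(rep1), 4L)          # 2 models x 2 scopes
  expect_true(all(is.na(rep1$error)))
  expect_true(all(rep1$rmsep >= 0))
  expect_length(attr(rep1, "residuals"), 4L)
  # identity rpd * rmsep = sd(prediction targets) holds per row
  resid <- attr(rep1, "residuals")
  for (k in names(resid))
    expect_equal(rep1$rpd[match(k, names(resid))] *
                   rep1$rmsep[match(k, names(resid))],
                 sd(resid[[k]]$target), tolerance = 1e-10)
  # bit-identical rerun under the same master config
  rep2 <- run_experiment(cfg)
  attr(rep1, "residuals") <- NULL; attr(rep2, "residuals") <- NULL
  expect_identical(rep1, rep2)
  # a failing cell is recorded, not fatal
  cfg_bad <- cfg
  cfg_bad$models <- c("plsr")
  cfg_bad$plsr_args <- list(lv_range = 500:600)
  repb <- run_experiment(cfg_bad)
  expect_true(all(!is.na(repb$error)))
})

test_that("preprocessing+selection strategies run end to end", {
  d <- simulate_dataset(mixture_design(levels = seq(0, 1, 0.125),
                                       adulterants = "rice_bran",
                                       replicates_per_level = 4L),
                        noise_model(seed = 8L), default_grid(30L))
  cfg <- list(data = d, models = "plsr",
              strategies = c("msc+cars", "snv+spa"), scopes = "combined",
              seeds = 1L, compute_rmsecv = TRUE, folds = 4L,
              plsr_args = list(lv_range = 1:4),
              cars_args = list(mc_runs = 15L),
              spa_args = list(min_vars = 2L, max_vars = 6L))
  rep <- run_experiment(cfg)
  expect_true(all(is.na(rep$error)))
  expect_equal(nrow(rep), 2L)
  expect_true(all(is.finite(rep$rmsecv)))
})
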