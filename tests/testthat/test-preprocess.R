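test_that("snv standardises each spectrum (sample sd) and is affine-invariant", {
  expect_equal(snv(matrix(c(1, 2, 3), 1)), matrix(c(-1, 0, 1), 1))
  set.seed(7)
  X <- matrix(rnorm(50), 5, 10)
  out <- snv(X)
  expect_equal(rowMeans(out), rep(0, 5), tolerance = 1e-10)
  expect_equal(apply(out, 1, sd), rep(1, 5), tolerance = 1e-10)
  # already standardised input is a fixed point
  expect_equal(snv(out), out, tolerance = 1e-10)
  # snv(a + b x) = snv(x), b > 0
  expect_equal(snv(3 + 2 * X), out, tolerance = 1e-10)
  expect_error(snv(matrix(1, 2, 4)), "constant")
})

test_that("msc removes exact affine scatter against the mean reference", {
  d <- tiny_set(n = 5L, p = 6L)
  t <- msc_fit(d)
  r <- t$reference
  expect_equal(r, colMeans(d$absorbance), ignore_attr = TRUE)
  # the reference itself is a fixed point
  expect_equal(drop(msc_apply(t, r)), r, ignore_attr = TRUE)
  # exact affine scatter is removed
  expect_equal(drop(msc_apply(t, 1 + 2 * r)), r, ignore_attr = TRUE,
               tolerance = 1e-12)
  # hand-solvable 5-point toy: x = 1 + 2 r exactly => a=1, b=2
  toy_r <- c(0, 1, 2, 3, 4)
  toy <- structure(list(kind = "msc", reference = toy_r,
                        fitted_on = "calibration"), class = "FittedTransform")
  expect_equal(drop(msc_apply(toy, c(1, 3, 5, 7, 9))), toy_r)
})

test_that("minmax uses calibration statistics only", {
  cal <- matrix(c(2, 4, 0, 10), 2, 2)
  t <- minmax_fit(cal)
  expect_equal(minmax_apply(t, cal), matrix(c(0, 1, 0, 1), 2, 2))
  # prediction rows may extrapolate outside [0, 1]
  expect_equal(minmax_apply(t, matrix(c(5, 5), 1)), matrix(c(1.5, 0.5), 1))
  # constant calibration column maps to zero
  t2 <- minmax_fit(matrix(c(3, 3, 1, 2), 2, 2))
  expect_equal(minmax_apply(t2, matrix(c(3, 7, 1, 2), 2, 2))[, 1], c(0, 0))
})

test_that("spxy_split matches the brute-force max-min oracle on small instances", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(4:8, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    y <- runif(n)
    d <- spectra_set(abs(X), seq(1000, 1200, length.out = 3),
                     y, rep("a", n))
    for (frac in c(0.5, 0.7)) {
      s <- spxy_split(d, frac)
      expect_equal(s$calibration_idx,
                   spxy_oracle(d$absorbance, y, max(2L, floor(frac * n))),
                   info = sprintf("seed %d frac %.1f", seed, frac))
      # partition property
      expect_equal(sort(c(s$calibration_idx, s$prediction_idx)), seq_len(n))
    }
  }
})

test_that("spxy produces the expected 84/21 split and brackets the target span", {
  d <- simulate_dataset(mixture_design(adulterants = "corn_flour"),
                        noise_model(seed = 5L))
  expect_equal(n_samples(d), 105L)
  s <- spxy_split(d, 0.8)
  expect_length(s$calibration_idx, 84L)
  expect_length(s$prediction_idx, 21L)
  # calibration targets bracket the full span (endpoint property)
  expect_equal(min(d$target[s$calibration_idx]), min(d$target))
  expect_equal(max(d$target[s$calibration_idx]), max(d$target))
  # two far outliers are always selected first
  set.seed(2)
  X <- matrix(rnorm(10 * 4), 10, 4)
  X[3, ] <- X[3, ] + 50
  X[8, ] <- X[8, ] - 50
  dd <- spectra_set(X - min(X), seq(1000, 1300, length.out = 4),
                    runif(10), rep("a", 10))
  so <- spxy_split(dd, 0.3)
  expect_true(all(c(3L, 8L) %in% so$calibration_idx))
  # degenerate: identical samples
  ddeg <- spectra_set(matrix(1, 4, 3), c(1000, 1100, 1200),
                      rep(0.5, 4), rep("a", 4))
  expect_error(spxy_split(ddeg, 0.5), "identical")
})

test_that("split_multi splits per adulterant group and merges", {
  d <- simulate_dataset(noise = noise_model(seed = 5L))
  s <- split_multi(d, 0.8)
  expect_length(s$calibration_idx, 336L)
  expect_length(s$prediction_idx, 84L)
  # each group contributes 84/21
  for (g in unique(d$adulterant)) {
    idx <- which(d$adulterant == g)
    expect_length(intersect(s$calibration_idx, idx), 84L)
  }
  # single group: identical to spxy_split
  one <- d[d$adulterant == "rice_bran", ]
  expect_equal(split_multi(one, 0.8)$calibration_idx,
               spxy_split(one, 0.8)$calibration_idx)
  # per-group floor: two groups of 5 at 0.8 -> 4 + 4
  set.seed(3)
  dd <- spectra_set(matrix(runif(10 * 3), 10, 3),
                    c(1000, 1100, 1200), runif(10),
                    rep(c("a", "b"), each = 5))
  expect_length(split_multi(dd, 0.8)$calibration_idx, 8L)
})
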