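test_that("reflectance and absorbance conversions follow their closed forms", {
  # R = (S - D) / (W - D)
  expect_equal(compute_reflectance(raw_scan(c(55), c(10), c(100))), 0.5)
  s <- raw_scan(c(100, 200, 300), c(5, 5, 5), c(100, 200, 300))
  expect_equal(compute_reflectance(s), rep(1, 3))           # S = W
  s <- raw_scan(c(7, 8), c(7, 8), c(70, 80))
  expect_equal(compute_reflectance(s), rep(0, 2))           # S = D
  expect_error(compute_reflectance(raw_scan(1, 2, 2)), "division by zero")

  # A = log10(1 / R)
  expect_equal(reflectance_to_absorbance(c(1, 0.1, 0.01)), c(0, 1, 2))
  expect_error(reflectance_to_absorbance(c(0.5, 0)), "index 2")
  expect_error(reflectance_to_absorbance(-0.1), "must be > 0")
})

test_that("scan -> reflectance -> absorbance inverts the forward model", {
  set.seed(1)
  p <- 20L
  A <- runif(p, 0, 2)
  D <- runif(p, 100, 200)
  W <- runif(p, 40000, 60000)
  S <- (W - D) * 10^(-A) + D        # so that (S - D)/(W - D) = 10^(-A)
  A_back <- reflectance_to_absorbance(compute_reflectance(raw_scan(S, D, W)))
  expect_equal(A_back, A, tolerance = 1e-10)
})

test_that("spectra_set validates its invariants", {
  X <- matrix(1, 3, 4)
  w <- c(1000, 1100, 1200, 1300)
  expect_s3_class(spectra_set(X, w, c(0, 0.5, 1), rep("a", 3)), "SpectraSet")
  expect_error(spectra_set(X, rev(w), c(0, 0.5, 1), rep("a", 3)),
               "strictly increasing")
  expect_error(spectra_set(X, w, c(0, 0.5, 1.2), rep("a", 3)), "\\[0, 1\\]")
  expect_error(spectra_set(X, w, c(0, 0.5), rep("a", 3)), "one entry per")
  expect_error(spectra_set(X, w, c(0, 0.5, 1), rep("a", 3),
                           sample_id = c("s", "s", "t")), "unique")
  X[2, 2] <- NA
  expect_error(spectra_set(X, w, c(0, 0.5, 1), rep("a", 3)), "finite")
})

test_that("truncate_range keeps the closed interval and is idempotent", {
  X <- matrix(seq_len(8), 2, 4)
  d <- spectra_set(X, c(900, 1000, 2400, 2500), c(0, 1), c("a", "b"))
  t1 <- truncate_range(d, 1000, 2400)
  expect_equal(as.numeric(t1$wavelengths), c(1000, 2400))
  expect_equal(t1$absorbance, d$absorbance[, 2:3],
               ignore_attr = TRUE)
  # idempotence
  t2 <- truncate_range(t1, 1000, 2400)
  expect_identical(t1$absorbance, t2$absorbance)
  # lo == hi keeps a single column
  t3 <- truncate_range(d, 1000, 1000)
  expect_equal(ncol(t3$absorbance), 1L)
  # full-range truncation is the identity on the default grid
  full <- tiny_set()
  expect_identical(truncate_range(full, 900, 1500)$absorbance, full$absorbance)
  expect_error(truncate_range(d, 1, 2), "no wavelengths")
})

test_that("CSV round trip is lossless and validates on read", {
  d <- tiny_set(n = 3L, p = 4L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(d, f)
  back <- read_spectra_csv(f)
  expect_equal(back$absorbance, d$absorbance, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(as.numeric(back$wavelengths), as.numeric(d$wavelengths))
  expect_identical(back$sample_id, d$sample_id)
  expect_identical(back$adulterant, d$adulterant)
  expect_equal(back$target, d$target)

  # corrupt target
  dt <- data.table::fread(f)
  dt$target[1] <- 1.2
  f2 <- withr::local_tempfile(fileext = ".csv")
  data.table::fwrite(dt, f2)
  expect_error(read_spectra_csv(f2), "\\[0, 1\\]")

  # shuffled wavelength columns
  dt <- data.table::fread(f)
  wcols <- setdiff(names(dt), c("sample_id", "adulterant", "target"))
  data.table::setcolorder(dt, c("sample_id", "adulterant", "target",
                                rev(wcols)))
  f3 <- withr::local_tempfile(fileext = ".csv")
  data.table::fwrite(dt, f3)
  expect_error(read_spectra_csv(f3), "increasing")

  # missing column
  dt <- data.table::fread(f)
  dt$adulterant <- NULL
  f4 <- withr::local_tempfile(fileext = ".csv")
  data.table::fwrite(dt, f4)
  expect_error(read_spectra_csv(f4), "adulterant")
})
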