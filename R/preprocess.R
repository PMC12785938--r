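# Preprocessing and calibration/prediction partitioning.
#
# All fitted transforms carry provenance: they are computed from calibration
# rows only and applied unchanged to prediction rows (leak-free order: split
# first, then fit).

.as_matrix <- function(x) {
  if (inherits(x, "SpectraSet")) x$absorbance
  else if (is.matrix(x)) x
  else matrix(x, nrow = 1L)
}

.with_matrix <- function(x, m) {
  if (inherits(x, "SpectraSet")) {
    x$absorbance <- m
    dimnames(x$absorbance) <- list(x$sample_id,
                                   format(unclass(x$wavelengths), trim = TRUE))
    x
  } else if (is.matrix(x)) m else drop(m)
}

#' Standard normal variate (SNV) correction
#'
#' Standardises each spectrum to mean 0 and sample (n-1) standard deviation 1.
#' Being per-spectrum, SNV needs no fitting and cannot leak information.
#'
#' @param x a numeric spectrum, an n x p matrix (rows are spectra), or a
#'   `SpectraSet`.
#' @return same shape/class as `x`, corrected.
#' @export
snv <- function(x) {
  m <- .as_matrix(x)
  if (ncol(m) < 2L) stop("SNV needs spectra of length >= 2")
  mu <- rowMeans(m)
  s <- apply(m, 1L, sd)
  if (any(s == 0))
    stop("constant spectrum (zero variance) in row ",
         paste(head(which(s == 0), 5L), collapse = ", "))
  .with_matrix(x, (m - mu) / s)
}

#' Fit a multiplicative scatter correction (MSC) transform
#'
#' The reference is the column-mean calibration spectrum r. Each spectrum x is
#' regressed as `x ~ a + b * r` by least squares and corrected to
#' `(x - a) / b`, removing additive and multiplicative scatter.
#'
#' @param calibration a `SpectraSet` or matrix of calibration spectra.
#' @return a `FittedTransform` of kind `"msc"`.
#' @export
msc_fit <- function(calibration) {
  m <- .as_matrix(calibration)
  if (!nrow(m)) stop("calibration set is empty")
  structure(list(kind = "msc", reference = colMeans(m),
                 fitted_on = "calibration"),
            class = "FittedTransform")
}

#' Apply a fitted MSC transform
#'
#' @param transform a transform from [msc_fit()].
#' @param x spectrum vector, matrix, or `SpectraSet`.
#' @return corrected object, same shape/class as `x`.
#' @export
msc_apply <- function(transform, x) {
  stopifnot(inherits(transform, "FittedTransform"), transform$kind == "msc")
  m <- .as_matrix(x)
  r <- transform$reference
  if (ncol(m) != length(r)) stop("spectrum length does not match the MSC reference")
  rc <- r - mean(r)
  denom <- sum(rc^2)
  out <- m
  for (i in seq_len(nrow(m))) {
    b <- sum((m[i, ] - mean(m[i, ])) * rc) / denom
    if (b == 0) stop("MSC slope b = 0 for row ", i, "; cannot invert")
    a <- mean(m[i, ]) - b * mean(r)
    out[i, ] <- (m[i, ] - a) / b
  }
  .with_matrix(x, out)
}

#' Fit a per-variable min-max normalisation
#'
#' Maps every calibration column into `[0, 1]`; prediction rows reuse the
#' calibration min/max and may fall outside the unit interval. A constant
#' calibration column maps to all zeros.
#'
#' @param calibration a `SpectraSet` or matrix of calibration spectra.
#' @return a `FittedTransform` of kind `"minmax_normalize"`.
#' @export
minmax_fit <- function(calibration) {
  m <- .as_matrix(calibration)
  if (!nrow(m)) stop("calibration set is empty")
  lo <- apply(m, 2L, min)
  hi <- apply(m, 2L, max)
  structure(list(kind = "minmax_normalize", min = lo, max = hi,
                 fitted_on = "calibration"),
            class = "FittedTransform")
}

#' Apply a fitted min-max normalisation
#'
#' @param transform a transform from [minmax_fit()].
#' @param x spectrum vector, matrix, or `SpectraSet`.
#' @return scaled object, same shape/class as `x`.
#' @export
minmax_apply <- function(transform, x) {
  stopifnot(inherits(transform, "FittedTransform"),
            transform$kind == "minmax_normalize")
  m <- .as_matrix(x)
  if (ncol(m) != length(transform$min))
    stop("variable count does not match the fitted normalisation")
  rng <- transform$max - transform$min
  scaled <- sweep(m, 2L, transform$min)
  pos <- rng > 0
  scaled[, pos] <- sweep(scaled[, pos, drop = FALSE], 2L, rng[pos], "/")
  scaled[, !pos] <- 0
  .with_matrix(x, scaled)
}

#' Identity transform (no preprocessing)
#' @return a `FittedTransform` of kind `"identity"`.
#' @export
identity_fit <- function() {
  structure(list(kind = "identity", fitted_on = "calibration"),
            class = "FittedTransform")
}

# ---- SPXY partitioning -----------------------------------------------------

#' SPXY calibration/prediction split
#'
#' Sample-set partitioning based on joint X-Y distances: Euclidean distances
#' on the spectra and absolute differences on the targets are each normalised
#' by their maximum, summed, and Kennard-Stone max-min selection is run on the
#' joint distance. The first two calibration samples are the pair at maximal
#' distance; each further calibration sample maximises its minimum distance to
#' the already-selected set (ties broken by lowest index). Selection stops at
#' `floor(fraction * n)` (at least 2) samples; the remainder is the prediction
#' set. By construction the extreme samples (including the extreme targets)
#' land in the calibration set.
#'
#' @param data a `SpectraSet`.
#' @param calibration_fraction fraction of samples for calibration, in (0, 1).
#' @return object of class `SplitResult` with `calibration_idx` and
#'   `prediction_idx` (1-based row indices into `data`).
#' @export
spxy_split <- function(data, calibration_fraction = 0.8) {
  stopifnot(inherits(data, "SpectraSet"))
  n <- n_samples(data)
  if (n < 3L) stop("SPXY needs at least 3 samples")
  if (!(calibration_fraction > 0 && calibration_fraction < 1))
    stop("calibration_fraction must be in (0, 1)")
  dx <- as.matrix(stats::dist(data$absorbance))
  dy <- abs(outer(data$target, data$target, "-"))
  mx <- max(dx); my <- max(dy)
  if (mx == 0 && my == 0) stop("all samples identical: SPXY distance is zero")
  d <- (if (mx > 0) dx / mx else 0) + (if (my > 0) dy / my else 0)
  n_cal <- max(2L, floor(calibration_fraction * n))
  # seed with the pair at maximal joint distance (lowest indices on ties)
  flat <- which(d == max(d), arr.ind = TRUE)
  flat <- flat[order(pmin(flat[, 1], flat[, 2]), pmax(flat[, 1], flat[, 2])), ,
               drop = FALSE]
  sel <- sort(unname(flat[1L, ]))
  while (length(sel) < n_cal) {
    rest <- setdiff(seq_len(n), sel)
    mind <- apply(d[rest, sel, drop = FALSE], 1L, min)
    sel <- c(sel, rest[which.max(mind)])  # which.max: lowest index on ties
  }
  structure(list(calibration_idx = sort(sel),
                 prediction_idx = setdiff(seq_len(n), sel)),
            class = "SplitResult")
}

#' Per-adulterant SPXY split
#'
#' Runs [spxy_split()] independently within each adulterant group and merges
#' the resulting index lists -- the construction of a multi-adulterant
#' calibration set from the per-type calibration subsets.
#'
#' @inheritParams spxy_split
#' @param fraction calibration fraction passed to each group's split.
#' @return a `SplitResult` with indices into the full `data`.
#' @export
split_multi <- function(data, fraction = 0.8) {
  stopifnot(inherits(data, "SpectraSet"))
  groups <- unique(data$adulterant)
  if (!length(groups)) stop("data has no adulterant labels")
  cal <- integer(0); pred <- integer(0)
  for (g in groups) {
    idx <- which(data$adulterant == g)
    s <- spxy_split(data[idx, ], fraction)
    cal <- c(cal, idx[s$calibration_idx])
    pred <- c(pred, idx[s$prediction_idx])
  }
  structure(list(calibration_idx = sort(cal), prediction_idx = sort(pred)),
            class = "SplitResult")
}

#' @export
print.SplitResult <- function(x, ...) {
  cat(sprintf("SplitResult: %d calibration / %d prediction samples\n",
              length(x$calibration_idx), length(x$prediction_idx)))
  invisible(x)
}
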