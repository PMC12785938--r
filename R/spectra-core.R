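#' @useDynLib incepspect, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats sd rnorm runif predict coef lm quantile cor setNames dist
#' @importFrom utils head tail
NULL

# ---- wavelength grid -------------------------------------------------------

#' Create a validated wavelength grid
#'
#' A wavelength grid is a strictly increasing numeric vector of wavelengths in
#' nanometres. It indexes the columns of every absorbance matrix in the
#' package.
#'
#' @param wavelengths_nm numeric vector, strictly increasing, finite, > 0,
#'   length >= 2.
#' @return numeric vector of class `WavelengthGrid`.
#' @export
wavelength_grid <- function(wavelengths_nm) {
  w <- as.numeric(wavelengths_nm)
  if (length(w) < 2L)
    stop("wavelength grid needs at least 2 points, got ", length(w))
  if (any(!is.finite(w)) || any(w <= 0))
    stop("wavelengths must be finite and > 0")
  if (any(diff(w) <= 0))
    stop("wavelengths must be strictly increasing")
  structure(w, class = "WavelengthGrid")
}

#' Default 213-point grid over 1000-2400 nm
#'
#' Evenly spaced grid matching the network input length used throughout the
#' package defaults.
#'
#' @param p number of points (default 213).
#' @param lo,hi range endpoints in nm.
#' @return a `WavelengthGrid`.
#' @export
default_grid <- function(p = 213L, lo = 1000, hi = 2400) {
  wavelength_grid(seq(lo, hi, length.out = p))
}

# ---- raw scans -------------------------------------------------------------

#' Bundle raw detector counts for one scan
#'
#' @param sample_signal,dark_signal,white_signal numeric vectors of detector
#'   counts, all the same length: the sample scan (S), dark reference (D) and
#'   white reference (W).
#' @return object of class `RawScan`.
#' @export
raw_scan <- function(sample_signal, dark_signal, white_signal) {
  p <- length(sample_signal)
  if (length(dark_signal) != p || length(white_signal) != p)
    stop("sample, dark and white signals must share one grid length")
  structure(list(sample_signal = as.numeric(sample_signal),
                 dark_signal   = as.numeric(dark_signal),
                 white_signal  = as.numeric(white_signal)),
            class = "RawScan")
}

#' Reflectance from raw counts
#'
#' Computes R = (S - D) / (W - D) per wavelength, the standard white-plate
#' referenced reflectance.
#'
#' @param scan a [raw_scan()] object.
#' @return numeric reflectance vector.
#' @export
compute_reflectance <- function(scan) {
  stopifnot(inherits(scan, "RawScan"))
  den <- scan$white_signal - scan$dark_signal
  bad <- which(den == 0)
  if (length(bad))
    stop("white and dark signals coincide (division by zero) at wavelength index ",
         paste(head(bad, 5L), collapse = ", "))
  (scan$sample_signal - scan$dark_signal) / den
}

#' Absorbance from reflectance
#'
#' A = log10(1 / R), the standard absorbance convention.
#'
#' @param reflectance numeric vector, all values > 0.
#' @return numeric absorbance vector.
#' @export
reflectance_to_absorbance <- function(reflectance) {
  bad <- which(!(reflectance > 0))
  if (length(bad))
    stop("reflectance must be > 0; offending wavelength index ",
         paste(head(bad, 5L), collapse = ", "))
  log10(1 / reflectance)
}

# ---- SpectraSet ------------------------------------------------------------

#' Construct a SpectraSet
#'
#' The universal data container of the pipeline: an n x p absorbance matrix on
#' a shared wavelength grid, with per-sample target mass fractions of the
#' genuine powder (in `[0, 1]`) and adulterant labels.
#'
#' @param absorbance numeric n x p matrix of absorbance values.
#' @param wavelengths wavelength grid (numeric, strictly increasing), length p.
#' @param target numeric vector of n mass fractions in `[0, 1]`.
#' @param adulterant character vector of n adulterant labels.
#' @param sample_id optional character vector of n unique sample identifiers;
#'   generated as `s0001`, ... when missing.
#' @return object of class `SpectraSet`.
#' @export
spectra_set <- function(absorbance, wavelengths, target, adulterant,
                        sample_id = NULL) {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  grid <- wavelength_grid(wavelengths)
  n <- nrow(absorbance)
  if (ncol(absorbance) != length(grid))
    stop("absorbance has ", ncol(absorbance), " columns but the grid has ",
         length(grid), " wavelengths")
  if (any(!is.finite(absorbance)))
    stop("absorbance must be finite")
  if (length(target) != n || length(adulterant) != n)
    stop("target and adulterant must have one entry per absorbance row")
  target <- as.numeric(target)
  if (any(target < 0 | target > 1))
    stop("targets must lie in [0, 1]; offending row ",
         paste(head(which(target < 0 | target > 1), 5L), collapse = ", "))
  if (is.null(sample_id))
    sample_id <- sprintf("s%04d", seq_len(n))
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop("sample_id values must be unique")
  if (length(sample_id) != n)
    stop("sample_id must have one entry per row")
  dimnames(absorbance) <- list(sample_id, format(unclass(grid), trim = TRUE))
  structure(list(absorbance = absorbance,
                 wavelengths = grid,
                 target = target,
                 adulterant = as.character(adulterant),
                 sample_id = sample_id),
            class = "SpectraSet")
}

#' @export
print.SpectraSet <- function(x, ...) {
  cat(sprintf("SpectraSet: %d samples x %d wavelengths (%.1f-%.1f nm)\n",
              nrow(x$absorbance), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  tab <- table(x$adulterant)
  cat("adulterants:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("target range: %.2f-%.2f\n", min(x$target), max(x$target)))
  invisible(x)
}

#' Number of samples / wavelengths in a SpectraSet
#' @param x a `SpectraSet`.
#' @return integer count.
#' @export
n_samples <- function(x) nrow(x$absorbance)

#' @rdname n_samples
#' @export
n_wavelengths <- function(x) length(x$wavelengths)

#' Subset a SpectraSet
#'
#' `i` selects sample rows, `j` wavelength columns; both keep their original
#' order semantics (a `j` subset must leave the grid strictly increasing).
#'
#' @param x a `SpectraSet`.
#' @param i row (sample) indices.
#' @param j column (wavelength) indices.
#' @param ... unused.
#' @return a `SpectraSet`.
#' @export
`[.SpectraSet` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_samples(x))
  if (missing(j)) j <- seq_len(n_wavelengths(x))
  spectra_set(x$absorbance[i, j, drop = FALSE],
              unclass(x$wavelengths)[j],
              x$target[i], x$adulterant[i], x$sample_id[i])
}

#' Restrict a SpectraSet to a wavelength window
#'
#' Keeps exactly the wavelengths in the closed interval `[lo_nm, hi_nm]`;
#' sample rows are untouched. Used to drop the noisy grid ends before
#' modelling (the conventional 1000-2400 nm window).
#'
#' @param data a `SpectraSet`.
#' @param lo_nm,hi_nm interval endpoints in nm, `lo_nm <= hi_nm`.
#' @return a `SpectraSet` on the restricted grid.
#' @export
truncate_range <- function(data, lo_nm, hi_nm) {
  stopifnot(inherits(data, "SpectraSet"))
  if (!(lo_nm <= hi_nm)) stop("lo_nm must be <= hi_nm")
  keep <- which(data$wavelengths >= lo_nm & data$wavelengths <= hi_nm)
  if (!length(keep))
    stop("no wavelengths inside [", lo_nm, ", ", hi_nm, "] nm")
  if (length(keep) == n_wavelengths(data)) return(data)
  if (length(keep) == 1L) {
    # single-column set: bypass the >=2 grid rule via direct construction
    out <- data
    out$absorbance  <- data$absorbance[, keep, drop = FALSE]
    out$wavelengths <- structure(unclass(data$wavelengths)[keep],
                                 class = "WavelengthGrid")
    return(out)
  }
  data[, keep]
}

# ---- CSV I/O ---------------------------------------------------------------

#' Read / write the canonical spectra CSV
#'
#' Wide layout, one row per sample: columns `sample_id`, `adulterant`,
#' `target`, then one column per wavelength named by its value in nm.
#'
#' @param path file path.
#' @return `read_spectra_csv` returns a `SpectraSet`.
#' @export
read_spectra_csv <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  need <- c("sample_id", "adulterant", "target")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("spectra CSV is missing column(s): ", paste(miss, collapse = ", "))
  wcols <- setdiff(names(dt), need)
  w <- suppressWarnings(as.numeric(wcols))
  if (any(is.na(w)))
    stop("non-numeric wavelength column header(s): ",
         paste(head(wcols[is.na(w)], 5L), collapse = ", "))
  if (any(diff(w) <= 0))
    stop("wavelength columns must be in strictly increasing order")
  spectra_set(as.matrix(dt[, wcols, drop = FALSE]), w,
              dt$target, dt$adulterant, dt$sample_id)
}

#' @rdname read_spectra_csv
#' @param data a `SpectraSet` to write.
#' @export
write_spectra_csv <- function(data, path) {
  stopifnot(inherits(data, "SpectraSet"))
  df <- data.frame(sample_id = data$sample_id,
                   adulterant = data$adulterant,
                   target = data$target,
                   check.names = FALSE, stringsAsFactors = FALSE)
  ab <- as.data.frame(data$absorbance)
  names(ab) <- format(unclass(data$wavelengths), trim = TRUE, digits = 15)
  rownames(ab) <- NULL
  data.table::fwrite(cbind(df, ab), path)
  invisible(path)
}
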