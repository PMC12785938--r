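# Synthetic mixture-spectra simulator.
#
# Emulates NIR absorbance spectra of a genuine plant powder adulterated with
# low-cost powders: shared Gaussian absorption bands (so endmembers overlap
# heavily, as real powder spectra do), Beer-Lambert-like linear mixing in
# absorbance, multiplicative scatter (gain), baseline offset and additive
# noise. Every stage of the pipeline is testable against this stated world.

#' Define a pure-component spectrum
#'
#' A component is a baseline offset plus a sum of Gaussian absorption bands
#' `amplitude * exp(-(lambda - center)^2 / (2 * width^2))`.
#'
#' @param name component label.
#' @param bands data.frame with columns `center_nm`, `width_nm`, `amplitude`.
#' @param baseline constant absorbance offset.
#' @return object of class `ComponentSpectrum`.
#' @export
component_spectrum <- function(name, bands, baseline = 0) {
  bands <- as.data.frame(bands)
  stopifnot(all(c("center_nm", "width_nm", "amplitude") %in% names(bands)))
  if (any(bands$width_nm <= 0)) stop("band widths must be > 0")
  if (any(bands$amplitude < 0)) stop("band amplitudes must be >= 0")
  structure(list(name = name, bands = bands, baseline = baseline),
            class = "ComponentSpectrum")
}

#' Evaluate a component's noiseless absorbance on a grid
#'
#' @param component a `ComponentSpectrum`.
#' @param grid a `WavelengthGrid`.
#' @return numeric absorbance vector, one value per grid point.
#' @export
endmember_absorbance <- function(component, grid) {
  stopifnot(inherits(component, "ComponentSpectrum"))
  w <- as.numeric(grid)
  a <- rep(component$baseline, length(w))
  for (k in seq_len(nrow(component$bands))) {
    b <- component$bands[k, ]
    a <- a + b$amplitude * exp(-(w - b$center_nm)^2 / (2 * b$width_nm^2))
  }
  a
}

# Band centers common to every default endmember: the classic NIR features of
# plant powders (C-H second/third overtones near 1200/1700 nm, water bands
# near 1420/1900 nm, combination bands near 2100 nm).
DEFAULT_BAND_CENTERS <- c(1200, 1420, 1700, 1900, 2100)
DEFAULT_BAND_WIDTHS  <- c(55, 50, 60, 55, 70)

#' Default endmembers: genuine powder plus four adulterants
#'
#' All five components share the same band centers and widths and differ only
#' in band amplitudes and baseline, so their spectra overlap heavily (pairwise
#' cosine similarity > 0.9) while remaining quantitatively distinguishable --
#' the regime that makes the calibration problem non-trivial.
#'
#' @return named list of five `ComponentSpectrum` objects: `pure` (the genuine
#'   powder), `corn_flour`, `wheat_bran`, `rice_bran`, `stem_powder`.
#' @export
make_default_endmembers <- function() {
  # Amplitudes chosen once against the qualitative structure of real powder
  # series: all pairwise cosine similarities within [0.90, 0.99 (stem 0.994)],
  # corn flour the most distinct from the pure powder (starch-rich: strong
  # 1700/2100 nm C-H bands, weak 1900 nm water band), stem powder the
  # closest (same plant).
  amps <- list(
    pure        = c(0.50, 0.62, 0.48, 0.88, 0.52),
    corn_flour  = c(0.22, 0.40, 0.72, 0.52, 0.80),
    wheat_bran  = c(0.62, 0.46, 0.30, 1.05, 0.38),
    rice_bran   = c(0.32, 0.85, 0.62, 0.60, 0.72),
    stem_powder = c(0.40, 0.52, 0.46, 0.92, 0.70))
  base <- c(pure = 0.35, corn_flour = 0.24, wheat_bran = 0.28,
            rice_bran = 0.42, stem_powder = 0.30)
  out <- lapply(names(amps), function(nm) {
    component_spectrum(nm,
                       data.frame(center_nm = DEFAULT_BAND_CENTERS,
                                  width_nm  = DEFAULT_BAND_WIDTHS,
                                  amplitude = amps[[nm]]),
                       baseline = base[[nm]])
  })
  names(out) <- names(amps)
  out
}

#' Mixture design: levels x adulterants x replicates
#'
#' @param levels mass fractions of the genuine powder, strictly increasing
#'   within `[0, 1]`. Default: 0 to 1 in 5% steps (21 levels).
#' @param adulterants adulterant names (must match endmember names).
#' @param replicates_per_level samples prepared per (adulterant, level) cell.
#'   Default 5, giving 105 samples per adulterant series and 420 in total.
#' @return object of class `MixtureDesign`.
#' @export
mixture_design <- function(levels = seq(0, 1, by = 0.05),
                           adulterants = c("corn_flour", "wheat_bran",
                                           "rice_bran", "stem_powder"),
                           replicates_per_level = 5L) {
  levels <- as.numeric(levels)
  if (any(levels < 0 | levels > 1)) stop("levels must lie in [0, 1]")
  if (any(diff(levels) <= 0)) stop("levels must be strictly increasing")
  if (replicates_per_level < 1L) stop("replicates_per_level must be >= 1")
  structure(list(levels = levels, adulterants = as.character(adulterants),
                 replicates_per_level = as.integer(replicates_per_level)),
            class = "MixtureDesign")
}

#' Measurement noise model
#'
#' A measured spectrum is `g * mix + offset + eps` with gain
#' `g ~ N(1, gain_sd)` (multiplicative scatter), baseline shift
#' `offset ~ N(0, offset_sd)` and i.i.d. `eps ~ N(0, additive_sd)` per
#' wavelength. Defaults are chosen so raw-spectrum PLSR is visibly degraded
#' and MSC/SNV help.
#'
#' @param additive_sd per-wavelength noise sd, absorbance units.
#' @param gain_sd sd of the multiplicative gain around 1.
#' @param offset_sd sd of the per-spectrum baseline shift, absorbance units.
#' @param seed integer RNG seed; `NA` draws from the current RNG state.
#' @return object of class `NoiseModel`.
#' @export
noise_model <- function(additive_sd = 0.005, gain_sd = 0.03,
                        offset_sd = 0.01, seed = NA_integer_) {
  if (additive_sd < 0 || gain_sd < 0 || offset_sd < 0)
    stop("noise standard deviations must be >= 0")
  structure(list(additive_sd = additive_sd, gain_sd = gain_sd,
                 offset_sd = offset_sd, seed = seed),
            class = "NoiseModel")
}

# draw one spectrum from the forward model using the *current* RNG state
.simulate_one <- function(fraction, adulterant_a, pure_a, noise) {
  g <- 1 + rnorm(1L, 0, noise$gain_sd)
  off <- rnorm(1L, 0, noise$offset_sd)
  eps <- rnorm(length(pure_a), 0, noise$additive_sd)
  g * (fraction * pure_a + (1 - fraction) * adulterant_a) + off + eps
}

#' Simulate a single mixture spectrum
#'
#' Linear (Beer-Lambert-like) mixing of the two endmembers at the given mass
#' fraction of the genuine powder, then the noise model is applied.
#'
#' @param fraction mass fraction of the genuine (pure) powder, in `[0, 1]`.
#' @param adulterant,pure `ComponentSpectrum` objects.
#' @param grid a `WavelengthGrid`.
#' @param noise a `NoiseModel`; if its `seed` is not `NA` the RNG is seeded
#'   first, making the draw deterministic.
#' @return numeric absorbance vector on `grid`.
#' @export
simulate_spectrum <- function(fraction, adulterant, pure,
                              grid = default_grid(), noise = noise_model()) {
  if (!is.finite(fraction) || fraction < 0 || fraction > 1)
    stop("fraction must lie in [0, 1]")
  if (!is.na(noise$seed)) set.seed(noise$seed)
  .simulate_one(fraction,
                endmember_absorbance(adulterant, grid),
                endmember_absorbance(pure, grid),
                noise)
}

#' Simulate a full adulteration dataset
#'
#' One sample per (adulterant, level, replicate) cell. With the defaults
#' (4 adulterants x 21 levels x 5 replicates) this yields n = 420 samples,
#' 105 per adulterant series. Targets equal the designed fractions exactly;
#' the whole draw is reproducible given `noise$seed`.
#'
#' @param design a [mixture_design()].
#' @param noise a [noise_model()]; its `seed` (when not `NA`) seeds the draw.
#' @param grid a `WavelengthGrid`.
#' @param endmembers named list of `ComponentSpectrum` objects containing
#'   `pure` plus every name in `design$adulterants`.
#' @return a `SpectraSet`.
#' @export
simulate_dataset <- function(design = mixture_design(),
                             noise = noise_model(),
                             grid = default_grid(),
                             endmembers = make_default_endmembers()) {
  stopifnot(inherits(design, "MixtureDesign"), inherits(noise, "NoiseModel"))
  if (!"pure" %in% names(endmembers))
    stop("endmembers must contain a component named 'pure'")
  miss <- setdiff(design$adulterants, names(endmembers))
  if (length(miss))
    stop("no endmember for adulterant(s): ", paste(miss, collapse = ", "))
  if (!is.na(noise$seed)) set.seed(noise$seed)
  pure_a <- endmember_absorbance(endmembers$pure, grid)
  n <- length(design$adulterants) * length(design$levels) *
    design$replicates_per_level
  X <- matrix(0, n, length(grid))
  target <- numeric(n)
  adulterant <- character(n)
  sample_id <- character(n)
  row <- 0L
  for (ad in design$adulterants) {
    ad_a <- endmember_absorbance(endmembers[[ad]], grid)
    for (lev in design$levels) {
      for (r in seq_len(design$replicates_per_level)) {
        row <- row + 1L
        X[row, ] <- .simulate_one(lev, ad_a, pure_a, noise)
        target[row] <- lev
        adulterant[row] <- ad
        sample_id[row] <- sprintf("%s_%03d_%d", ad, round(100 * lev), r)
      }
    }
  }
  spectra_set(X, as.numeric(grid), target, adulterant, sample_id)
}
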