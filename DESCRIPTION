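Package: incepspect
Title: Quantitative NIR Calibration for Adulterated Plant Powders
Version: 0.1.0
Authors@R:
    person("Analytics", "Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A complete near-infrared (NIR) calibration pipeline for
    quantifying the mass fraction of a genuine plant powder in adulterated
    mixtures. Provides spectral I/O and reflectance-to-absorbance conversion,
    SPXY calibration/prediction partitioning, MSC/SNV/min-max preprocessing,
    CARS and SPA wavelength selection, PLSR and RBF-SVR baseline models, and
    a one-dimensional convolutional network combining multi-scale Inception
    blocks, a convolutional block attention module (CBAM) and a residual
    shortcut, trained with AdamW on an L2-regularised squared-error loss.
    A built-in simulator generates mixture spectra with realistic absorption
    bands, multiplicative scatter and noise so the whole pipeline is testable
    without proprietary spectrometer data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
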