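Package: nucdyn
Title: Nuclear Segmentation, Tracking and Dispersion Kinetics for Epithelial Time-Lapse Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for apical-basal nuclear dispersion in columnar
    epithelia imaged by 3D fluorescence time-lapse microscopy. Provides 3D
    nuclear segmentation (isotropic resampling, local thresholding,
    erosion-derived seeds, gradient seeded watershed), overlap-based track
    linking, half-max midplane depth metrics with apical-zone occupancy
    fractions, rolling-window mean-squared-displacement classification of
    active nuclear motion via the anomalous-diffusion exponent, one-phase
    association FRAP fitting (half-time and immobile fraction), ROI intensity
    quantitation with background, bleach and outlier corrections, and a
    synthetic-microscopy generator with ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
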