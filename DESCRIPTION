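Package: grasstrend
Title: Grassland Aboveground-Biomass Dynamics from NDVI Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates grassland aboveground biomass (AGB) from NDVI and
    analyses its spatiotemporal dynamics. Computes narrow-band NDVI from
    field canopy reflectance spectra, calibrates satellite NDVI against
    field measurements by comparing four regression families (linear,
    exponential, logarithmic, power), fits grassland-type-specific
    NDVI-to-AGB models, composites raster time series by annual maximum
    value, classifies per-pixel linear trends, estimates the Hurst exponent
    by rescaled-range (R/S) analysis to judge trend sustainability, and
    combines trend and sustainability into a future-dynamics
    classification. A synthetic-data generator (plot surveys, paired
    calibration NDVI, raster stacks with prescribed trend and fractional
    Gaussian noise) makes every stage testable without satellite archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
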