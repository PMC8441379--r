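Package: tlsrhythm
Title: Seasonal and Circadian Rhythms in Plant Structural Traits from
    Terrestrial Laser Scanning
Version: 0.1.0
Authors@R:
    person("tlsrhythm", "developers", email = "tlsrhythm@example.org",
           role = c("aut", "cre"))
Description: Tools to study seasonal and circadian rhythms in crop structural
    traits measured by terrestrial laser scanning (TLS). Includes a parametric
    generator of labeled maize point clouds with known ground truth (logistic
    seasonal growth, sinusoidal circadian modulation, diurnal
    PAR/temperature/humidity series), point-cloud input/output (ASCII XYZ,
    binary PLY, LAS read) and preprocessing (box clipping, statistical outlier
    removal, digital-terrain-model height normalization, planting-grid plant
    clustering), nine plant-level and nine leaf-level structural traits
    (height quantiles, crown size, eigenvector azimuth, projected leaf area,
    convex-hull volume, projected area index, vertical profile index, and
    midrib-slicing leaf morphometrics), and rhythm statistics (Tukey multiple
    comparisons with compact letter displays, hourly-growth de-trending of
    circadian series, natural cubic-spline interpolation of environmental
    records, and Pearson environment-trait correlation with significance
    tiers).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    stats,
    tools,
    utils,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
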