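Package: nanovario
Title: Variogram-Based Nanoscale Texture Analysis of AFM Height Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Texture analysis of atomic force microscopy (AFM) height, amplitude
    and phase rasters of histological sections. Computes residuals of truncated
    Gaussian filtering, directional 2D RMS-deviation maps, radially binned
    empirical variograms and their generalized q-moments, plateau sill estimates,
    facet inclination (theta) statistics, and a comparison battery of surface
    statistics, rescaled-range Hurst exponents and monofractal dimension
    estimators. Per-sample sill indexes feed a two-group midpoint-threshold
    classifier with Welch t-test group separation, aimed at indexing metastatic
    versus non-metastatic tissue texture. Includes seed-deterministic synthetic
    surface generators (analytic fields, fractional Brownian surfaces, two-class
    tissue phantoms) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    yaml
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
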