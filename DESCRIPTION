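Package: dendrolake
Title: Tree-Ring Chronologies, Drought Indices and Lake-Level
    Reconstruction for Lakeshore Stands
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Dendrohydrological toolkit for reconstructing lake and
    groundwater levels from tree-ring chronologies of riparian trees.
    Builds site master chronologies from ring-width series (cubic
    smoothing-spline detrending with a 50% frequency cutoff, horizontal
    standardization, Tukey biweight robust means) with the standard
    quality statistics (RBAR, mean sensitivity, first-order
    autocorrelation, EPS and running EPS); computes Thornthwaite
    potential evapotranspiration, the climatic water balance and the
    Standardized Precipitation-Evapotranspiration Index (SPEI) at
    multiple accumulation scales; aggregates monthly series over
    hydrological water years; and fits and verifies lagged linear
    reconstruction models of lake or groundwater level from ring-width
    index and SPEI predictor pools. A seeded synthetic-data generator
    emulates a temperate-humid multi-lake study design so the whole
    pipeline is testable without external data. Reads and writes
    Tucson/RWL decadal ring-width files and long-format monthly CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
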