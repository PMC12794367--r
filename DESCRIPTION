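Package: forestcarbon
Title: Integrated Monitoring of Forest Carbon Stocks and Fluxes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrative toolkit for high-resolution forest carbon
    monitoring: delineation of eco-functional clusters from mixed
    categorical/continuous landscape rasters (k-prototypes with
    silhouette-based model selection), canopy-height allometric
    aboveground-biomass and carbon baselines, post-processing of
    half-hourly eddy-covariance net ecosystem exchange (quality
    screening, friction-velocity threshold filtering with bootstrap
    uncertainty, flux-footprint climatologies, ensemble-tree gap
    filling, flux partitioning, and full uncertainty budgets),
    satellite-proxy upscaling of gross primary production and
    ecosystem respiration to 8-day 30-m flux maps, a median-ratio
    spatial extrapolation factor, and an append-only hash-chained
    carbon-unit registry for property-level accounting. Ships seeded
    synthetic-data generators with known generative truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
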