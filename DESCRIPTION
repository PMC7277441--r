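Package: lcsaccess
Title: Spatial Accessibility of Lung Cancer Screening Providers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for small-area spatial accessibility analysis
    of low-dose computed tomography (LDCT) lung cancer screening providers.
    Ingests Medicare-style provider utilization tables, builds fixed-radius
    Euclidean buffers in an equal-area planar projection, applies an area-fraction
    served rule at the census-tract level, aggregates provider counts to counties,
    computes provider densities per 1000 beneficiaries, and classifies counties on
    a 3x3 bivariate tertile scheme against smoking prevalence. Includes a seeded
    synthetic-geography generator emulating the structural properties of the
    national data (suppression of low-volume providers, zero-population tracts,
    spatially autocorrelated smoking surfaces) with planted ground truth for
    recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    geosphere,
    ggplot2,
    mgcv,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
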