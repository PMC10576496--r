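Package: reefmorph
Title: Colony-Scale Structural Complexity and Compositional Regression for
    Coral Elevation Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Terrain analysis of coral-colony digital elevation models and
    compositional regression of structure on benthic cover. Computes surface
    rugosity, fractal dimension from multiscale geodesic surface area, and
    Zevenbergen-Thorne slope, planform and profile curvature on square-celled
    elevation rasters; quantifies Live/Dead/Other benthic composition from
    categorical masks; and relates the five structural metrics to composition
    through rounded-zero replacement, pivot log-ratio coordinates and least
    trimmed squares robust regression. A seeded synthetic-data module
    (fractional Brownian surfaces, smoothed categorical masks, Dirichlet
    compositions) provides ground-truth inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
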