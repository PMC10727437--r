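Package: azollatpc
Title: Thermal Performance Curves and Habitat Suitability Projection for Azolla
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Harmonizes literature-derived temperature-growth records for
    Azolla species, fits an asymmetric piecewise-Gaussian thermal performance
    curve (the Room model) per species by maximum likelihood with a
    study-level random effect on peak height marginalized by Gauss-Hermite
    quadrature, and projects fitted curves onto gridded annual-mean-temperature
    rasters to produce habitat-suitability maps and regional change summaries
    under climate scenarios. Includes a synthetic-data generator for
    multi-study growth datasets and temperature rasters with known ground
    truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    readxl,
    yaml,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
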