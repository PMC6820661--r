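Package: flowabc
Title: Bead-Calibrated Quantitative Immunophenotyping of Cytometry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for quantitative flow cytometry
    immunophenotyping: simulation of plate-based single-stain experiments,
    conversion of PE fluorescence to antibody binding capacity (ABC) through
    a four-level calibration-bead curve, per-antibody conjugation correction
    factors, threshold gating with event-count quality control, FMO-anchored
    percent positivity, per-subset expression statistics, logistic modelling
    of rank-ordered positivity, Menger-curvature turning points on ordered
    expression sequences, hierarchical clustering of subset expression
    profiles, and rank-based differential marker comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
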