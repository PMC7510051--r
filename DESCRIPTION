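Package: fungalscape
Title: Regional Soil Mycobiome Survey Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tidyverse-native pipeline for regional soil fungal
    metabarcoding surveys: sample and OTU quality control with
    mold-spoilage screening, rank-thresholded taxonomic assignment from
    best-hit tables and functional annotation from a traits lookup,
    diversity transforms (anchored percentage log-ratio, Hellinger,
    Shannon, depth-residual richness, analytic rarefaction), Gaussian
    niche modelling of richness and per-OTU abundance along environmental
    gradients with random-forest predictor preselection and
    response-shape classification, distance-based community structure
    statistics (PERMANOVA, NMDS, Moran eigenvector maps, plant-phylogeny
    community distances), and checkerboard C-score co-occurrence
    analysis. Includes a synthetic-survey generator with known ground
    truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    picante,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
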