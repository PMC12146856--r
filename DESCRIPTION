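Package: roadbias
Title: Quantifying Roadside Sampling Bias in Species Occurrence Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the "road-map effect" -- the dependence of the
    geography of biological collections on road networks -- from occurrence
    records and period-specific road maps. Implements three complementary
    measures: a Monte-Carlo null-model test on mean nearest-road distance with
    a gamma distance-decay index, a binomial buffer-clustering statistic
    (P_clustering) at regional and county scale, and a road-density null-model
    test around records. Includes a spatially explicit random-forest covariate
    analysis with stepwise pseudo-AIC selection, permutation importance, PCNM
    (principal coordinates of neighbour matrices) spatial filters and Moran's I
    residual diagnostics, plus a synthetic-data generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    ranger,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    fitdistrplus,
    randomForest,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
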