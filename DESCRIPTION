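Package: lwcspec
Title: Leaf Water Content Estimation from VIS-NIR Canopy Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for estimating crop leaf water content (LWC) from
    visible/near-infrared canopy reflectance spectra. Implements
    Grunwald-Letnikov fractional-order derivative (FOD) spectral
    preprocessing, morphological spectral smoothing, a catalogue of fixed
    two-band moisture indices, exhaustive two- and three-band spectral-index
    optimization by Pearson correlation with the trait, and a calibration /
    validation machine-learning layer (KNN, SVR, single-hidden-layer ANN)
    evaluated by R-squared, RMSE and RPD. A self-contained synthetic canopy
    spectra generator provides reproducible datasets with water-absorption
    features and optional planted index signals for recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    nnet,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
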