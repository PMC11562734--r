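Package: ilscreen
Title: Ionic Liquid Property Prediction and Screening with Representation Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative structure-property relationship (QSPR) modelling of
    ionic liquids from cation/anion SMILES pairs, using four molecular
    representations (count and binary substructure fingerprints, physicochemical
    descriptor vectors, 2D depiction images, and molecular graphs) with one
    regressor per representation. Prediction reliability is quantified two ways:
    model uncertainty (spread over hyperparameter variants of one representation)
    and representation uncertainty (spread over the four representation models),
    with Tukey-fence reliability thresholds calibrated on training-set
    uncertainties. Includes an equal-weight four-model ensemble, a cross-product
    out-of-distribution "non-IL" benchmark, a sequential multi-property screening
    pipeline, and a synthetic ion-pair data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    igraph,
    methods,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    jsonlite,
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
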