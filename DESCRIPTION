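Package: cardiofit
Title: Curve-Fitting Cascade and Neural-Network Models for Heart-Disease
    Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identification of heart-disease patients from 13 routine
    clinical features via two closed-form models: a sequential residual
    curve-fitting cascade that yields an additive linear correlation, and a
    single-hidden-layer feedforward neural network with tansig hidden and
    purelin output activations, trained from scratch by full-batch gradient
    descent with early stopping and a hidden-size sweep. Includes min-max
    feature standardization with invertible parameters, published frozen
    coefficients for both models, regression and classification metrics
    (coefficient of determination, MAE, RMSE, confusion counts), permutation
    feature importance, and a synthetic tabular data generator with known
    ground truth for benchmarking every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
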