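Package: conformalsig
Title: Conformal Prediction and Venn-ABERS Calibration for QSAR Models
    Built on Molecular Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Confidence-calibrated QSAR modeling. Implements mondrian
    (class-conditional) inductive, aggregated, cross and transductive
    conformal predictors for classification, inductive and aggregated
    conformal regression with error-model-normalized nonconformity
    measures, and inductive/cross Venn-ABERS probabilistic calibration,
    on top of the circular molecular Signatures descriptor with
    atom-level interpretation of individual predictions. Includes
    conformal-specific evaluation metrics (calibration curves, observed
    fuzziness, efficiency), validation strategies and grid-search
    hyper-parameter tuning, plus a command-line workflow for
    precomputing descriptors, training, validating and predicting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    e1071,
    glmnet,
    jsonlite,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
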