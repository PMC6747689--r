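Package: dilivote
Title: Weighted Soft-Voting Ensembles for Drug-Induced Liver Injury
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A QSAR toolkit for binary drug-induced liver injury (DILI)
    classification from precomputed molecular fingerprint and
    physicochemical descriptor tables. Evaluates a grid of nine machine
    learning algorithms over twelve fingerprint families by repeated
    stratified cross-validation, performs two-tier selection (top
    algorithms by per-fingerprint top-5 counts, fingerprints by greedy
    forward addition), and fits a weighted dual-block soft-voting
    ensemble that fuses a fingerprint-side and a descriptor-side
    probability estimate. Includes a synthetic data generator with a
    planted, analytically tractable class signal for end-to-end
    validation without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    caret,
    ChemmineR,
    e1071,
    glmnet,
    jsonlite,
    randomForest,
    ranger,
    rpart,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
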