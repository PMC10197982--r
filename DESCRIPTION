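Package: hyperkECG
Title: Predicting Hyperkalemia from ECG Morphology with Machine Learning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reproducible pipeline for electrocardiographic prediction of
    hyperkalemia in dialysis populations: WFDB-style record input/output
    (Format 212), baseline-drift correction and wavelet/band-pass
    preprocessing, beat delineation and extraction of 48 morphological
    features from chest leads V2-V5, binary classification of serum
    potassium at multiple diagnostic thresholds with five model families
    (logistic regression, RBF support-vector machine, gradient-boosted
    trees, AdaBoost stumps, and a small 1-D convolutional network), and
    ROC-based model comparison with DeLong confidence intervals and paired
    DeLong tests. A potassium-modulated synthetic ECG generator provides
    labeled data with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    e1071,
    xgboost,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
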