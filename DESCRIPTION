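Package: perfrad
Title: Perfusion Radiomics for Assessing Neurological Impairment in Acute
    Ischemic Stroke
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for assessing neurological impairment
    (dichotomized NIHSS) in acute ischemic stroke from co-registered
    perfusion parameter maps (CBF, CBV, MTT, Tmax). Delineates ischemic
    (Tmax > 6 s), infarct (ADC < 620e-6 mm^2/s from a DWI pair) and hypoxic
    regions (QSM-derived venous oxygen saturation on a mirrored hemisphere
    grid), extracts an IBSI-style radiomics feature battery (first order and
    five gray-level texture matrix families over a filter bank of
    Laplacian-of-Gaussian, wavelet and intensity-remap images), selects
    features by two-sample t-test plus cross-validated Lasso, and benchmarks
    a six-classifier panel (SVM, MLP, RF, AdaBoost, LR, Gaussian NB) with
    accuracy, sensitivity, specificity, PPV, NPV and AUC on a stratified 7:3
    split. Ships a synthetic multi-modal cohort generator so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    e1071,
    nnet,
    randomForest,
    rpart,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
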