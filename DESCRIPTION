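Package: strokenlp
Title: Phenotyping Ischemic Stroke from Radiology Report Text
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: End-to-end natural language processing pipeline for classifying
    unstructured neuroimaging reports: text cleaning and medical phrase
    merging, bag-of-words / tf-idf / GloVe featurization (including training
    domain word embeddings from a plain-text corpus), binary classifiers
    (lasso logistic regression, k-nearest neighbours, CART, random forest,
    and a hierarchical LSTM document model), and an evaluation protocol with
    repeated stratified 75/25 splits, grid-search cross-validation, ROC/AUC
    with confidence intervals, sensitivity-first operating thresholds,
    calibration tables, and McNemar model comparison. A synthetic
    neuroradiology report generator with controllable signal supplies
    labelled corpora for development and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    data.table,
    glmnet,
    jsonlite,
    methods,
    randomForest,
    rpart,
    stats,
    tibble,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
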