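Package: entrogait
Title: Entropy-Based Complexity Features and Imbalanced Nested
    Cross-Validation for EMG and Gait Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Extracts regularity and complexity features (approximate,
    sample, fuzzy, spectral and conditional entropy, plus a
    decimation-based multiscale scheme) from surface electromyography and
    three-axis gait kinematic time series, and evaluates their ability to
    discriminate stroke survivors from able-bodied controls with a
    repeated class-balanced, ten-fold nested cross-validation framework:
    in-loop minimum-redundancy maximum-relevance feature selection,
    hyperparameter search over seven classifier families, DeLong tests
    between correlated ROC curves, and unpaired group t-tests. A
    synthetic cohort generator emulating burst-modulated gastrocnemius
    EMG coupled to quasi-periodic calcaneus trajectories makes the whole
    pipeline testable without access to motion-capture recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    rpart,
    glmnet,
    e1071,
    randomForest,
    nnet,
    class,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
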