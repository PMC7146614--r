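Package: spastimu
Title: Grading Elbow Spasticity from Wearable Inertial Sensor Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for machine-learning assessment of elbow spasticity on
    the modified Ashworth scale (MAS) from triaxial accelerometer and
    gyroscope recordings of passive stretch tests. Simulates labeled
    passive-stretch cohorts, trims quasi-static baselines, extracts the middle
    three flexion-extension cycles, windows them with and without 50% overlap,
    computes time- and frequency-domain feature sets (including roll/pitch,
    signal magnitude area and signal vector magnitude), evaluates decision
    tree, random forest, SVM, LDA and multilayer perceptron classifiers under
    leave-one-out cross-validation, and compares conditions with exact
    Wilcoxon signed-rank tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    nnet,
    rpart,
    randomForest,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
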