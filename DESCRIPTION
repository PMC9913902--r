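Package: spidermri
Title: Brain-Tumor MRI Screening via Social Spider Optimization
    Thresholding, SVD Features and a Voting Ensemble
Version: 0.1.0
Authors@R:
    person("spidermri", "maintainers", email = "spidermri@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for binary brain-tumor screening on 2-D
    grayscale MRI slices: background removal by intensity binarization,
    largest-connected-component selection and hole filling; multilevel
    thresholding segmentation driven by a Tsallis-entropy objective and
    searched with the Social Spider Optimization metaheuristic (with an
    exhaustive-enumeration oracle for small instances); singular value
    decomposition feature extraction with a 99 percent energy rank rule;
    and a majority-vote ensemble of a linear support vector machine,
    Gaussian naive Bayes and 3-nearest-neighbour classifiers. Includes a
    synthetic head-phantom generator with ground-truth masks, repeated
    stratified holdout and k-fold evaluation with confusion-matrix rates
    and ROC/AUC, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    jsonlite,
    yaml,
    quadprog,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
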