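Package: operonvoter
Title: Operon Pair Prediction from RNA-Seq Coverage by Ensemble Threshold Voting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts whether adjacent bacterial genes are co-transcribed
    (operon pairs) from short-read RNA-seq per-base coverage. Coverage over
    the terminal windows of each gene and the central intergenic window is
    compared with Kruskal-Wallis rank tests; the resulting statistics,
    log10 p-values, gene lengths, intergenic distance and strand match form
    a 12-dimensional feature vector. Six binary classifiers (logistic
    regression, RBF-kernel support vector machine, random forest, gradient
    boosted trees, a multilayer perceptron and Gaussian naive Bayes) are
    trained on labelled pairs and combined by threshold voting (1-6 votes),
    with optional replicate-consensus filtering and chaining of consecutive
    positive pairs into multi-gene operons. Includes a seeded synthetic
    genome and coverage simulator, bootstrap evaluation utilities, Gaussian
    process hyperparameter optimization, and a command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    ranger,
    xgboost,
    e1071,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
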