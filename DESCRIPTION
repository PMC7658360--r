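Package: llgmn
Title: Mood Disorder Screening with Log-Linearized Gaussian Mixture Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probabilistic screening of post-stroke mood disorders (depression,
    apathy, anxiety) from tabular neuropsychological and functional evaluation
    indices. Implements the log-linearized Gaussian mixture network (LLGMN)
    classifier with quadratic input expansion and error-backpropagation
    training, greedy backward input-dimensionality reduction scored by the
    partial Kullback-Leibler information ratio, ROC/AUC evaluation with
    balanced ten-fold cross-validation, paired AUC comparison via the DeLong
    test with Holm adjustment, three linear reference classifiers (stepwise
    linear regression, ridge-regularised logistic regression, partial least
    squares regression), a synthetic post-stroke cohort generator with
    group-conditional index distributions and threshold-derived disorder
    labels, and a pipeline orchestrating the full per-disorder analysis
    including single-index ablation ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    glmnet,
    mixOmics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
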