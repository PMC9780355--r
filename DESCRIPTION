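Package: shortcutsim
Title: Simulating Shortcut Learning Through Demographic Confounding in
    Medical Imaging AI
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying how a classifier can appear to predict a
    demographic label (such as binary race) by exploiting a predictable
    confounder (such as sex or age group) that is unevenly distributed in
    the training data.  Provides a synthetic patient-cohort generator with
    exactly calibrated Gaussian feature signal per demographic attribute,
    patient-level splitting, bias-controlled training-set construction, a
    regularized linear surrogate for per-view imaging models and their
    logistic ensemble, AUROC and mean-absolute-error metrics with
    percentile bootstrap confidence intervals, a closed-form oracle for
    confounder-mediated AUROC, a comorbidity-based logistic benchmark for
    race prediction, and an orchestrated bias-sweep experiment with
    tabular, JSON and graphical reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
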