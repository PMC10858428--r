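Package: adpheno
Title: Atopic Dermatitis Patient Phenotyping from Clinical Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for phenotyping atopic dermatitis (AD)
    patients from free-text clinical notes. Documents are split into sentences,
    matched against eight AD-indicator lexicons, and each match is assigned an
    assertion status (affirmed, negated, other-experiencer, hypothetical) with a
    ConText-style trigger/scope rule set. Sentence evidence is collapsed into an
    8-element patient vector either as binary indicator flags or as max-aggregated
    affirm probabilities from per-category multilayer perceptron sentence
    classifiers over sentence embeddings. Downstream phenotype classifiers
    (logistic regression, SVM, decision tree, random forest, k-nearest
    neighbours, gradient boosting, AdaBoost, and a stacking ensemble) are tuned
    by 5-fold cross-validation and evaluated with accuracy, precision, recall,
    F1, NPV and specificity on balanced and prevalence-matched test sets. A
    synthetic clinical-note generator with UK Working Party gold labels and
    configurable noise makes every stage testable without access to protected
    health records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    withr,
    e1071,
    rpart,
    randomForest,
    class,
    xgboost,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
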