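Package: oncodss
Title: Pathology Report Feature Extraction and Division-of-Labor Clinical
    Decision Support
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two linked clinical-informatics workflows in oncology.
    First, rule-based extraction of TNM staging parameters (T, N, M, L, V, R,
    lymph-node counts), ICD-10 tumor localization, and a bag-of-words
    L1-regularized logistic classifier for neoadjuvant-therapy status from
    free-text pathology findings, with a three-class return contract
    (concrete, ambiguous, empty), provenance spans, certainty banding, and a
    headless expert-validation workflow that feeds corrections back into
    model retraining. Second, a Division-of-Labor decision-support framework
    that segments a patient cohort, trains one online Expert per segment
    (six therapy-decision classifiers plus LASSO attribute-importance
    models), routes queries to the nearest Expert, and benchmarks the
    ensemble against standalone classifiers with cross-validated F1 scores.
    Synthetic generators for templated pathology findings and for tabular
    patient cohorts with latent segment structure make both pipelines fully
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    rpart,
    e1071,
    stats,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
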