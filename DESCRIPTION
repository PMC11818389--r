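Package: rfablate
Title: Surrogate Lesion-Index Models and Stopping-Rule Comparison for
    Radiofrequency Ablation Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing per-lesion radiofrequency (RF) ablation
    traces from contact-force and local-impedance (LI) sensing catheters.
    Implements configurable reference formulas for the Ablation Index (AI)
    and Lesion Size Index (LSI), per-timepoint surrogate regression models
    (random forest, gradient boosting, penalised linear families) that
    predict the indices from trace features, trace processing (997 Hz
    resampling, 1.5 s moving-mean LI filtering, LI-drop plateau detection,
    interlesion distances), and a cohort comparison of RF application
    durations across AI-, LSI-, and LI-plateau stopping rules (Friedman and
    post-hoc Wilcoxon signed-rank tests, chained-equations imputation of
    missing LSI durations, predictor-importance analysis with GAMs and
    random forests). Includes a synthetic-cohort generator with ground-truth
    indices so every stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    lmtest,
    mgcv,
    nortest,
    ranger,
    stats,
    utils,
    xgboost
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
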