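Package: omcdr
Title: Optimal Model Complexity Models for Cancer Drug-Response Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds concise, cancer-specific drug-response regression models
    from multi-omics feature matrices of cell-line panels. Implements
    rank-stratified external test-set extraction and five-fold
    cross-validation, fold-wise univariate feature ranking (Wilcoxon
    rank-sum for binary mutation/copy-number features, Spearman
    rank-correlation for expression and methylation features), a nested
    top-k model-complexity search with per-fold Spearman performance
    gates, gradient-boosted regression trees as the base learner,
    y-randomization validation, and a seeded synthetic-data generator
    with planted informative features for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    xgboost,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
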