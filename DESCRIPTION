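Package: mirwoi
Title: miRNA Panel-qPCR Classification of the Endometrial Window of
    Implantation
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for building and evaluating a microRNA-based classifier of
    the endometrial window of implantation from panel-qPCR Cq profiles.
    Implements Cq-table input with explicit non-amplification handling,
    replicate averaging, quantile normalization with frozen references,
    low-amplification filtering, maximum-deltaCq imputation, feature scaling
    and PCA, an elastic-net-penalized ordinal score fitted by coordinate
    descent with ten-fold cross-validated tuning, threshold mapping of the
    score to three embryo-transfer-time states (108/120/144 h of progesterone
    exposure), three-class confusion-matrix metrics, concordance analysis
    stratified by previous implantation failures, a differential-expression
    screen, and a synthetic cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    glmnet,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
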