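Package: sensig
Title: Biomarker Signature Discovery by KLD-Scored SVM Backward Elimination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and validation of transcriptomic biomarker signatures
    that separate skin-sensitizing from non-sensitizing chemicals. Implements
    per-transcript one-way ANOVA filtering with Benjamini-Hochberg FDR
    correction, wrapper-based backward elimination of analytes scored by the
    Kullback-Leibler divergence of leave-one-out cross-validated linear SVM
    class-probability predictions with breakpoint detection, stratified
    compound-level resampling validation with ROC/AUC, principal-component
    projection of held-out samples, and a synthetic expression-data generator
    that emulates the sample design of a 40-compound dendritic-cell-line
    stimulation study.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    e1071,
    pROC,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
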