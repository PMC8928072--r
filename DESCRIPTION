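Package: immunopanel
Title: Immune Activation/Checkpoint Panel Scoring and ICB Response Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-sample gene-set enrichment (ssGSEA) scoring of a 15-gene
    immune activation and checkpoint panel, a rank-based predictor of response
    to immune checkpoint blockade with ROC/AUC evaluation, the statistical
    comparisons used to validate the panel (two-sided Wilcoxon rank-sum tests,
    Pearson correlations, stratified tables), and a synthetic bulk-expression
    cohort generator with a latent immune-infiltration factor for end-to-end
    testing of the whole pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
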