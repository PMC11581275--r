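Package: radmir
Title: Radiation-Responsive miRNA Biomarker Discovery and Panel Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for discovering circulating miRNA biomarkers of
    total-body irradiation from small-RNA-seq count data. Covers negative
    binomial cohort simulation with planted dose-, time-, sex- and
    survival-linked effects, TMM/CPM normalization with per-animal log2
    fold changes against pre-irradiation baselines, four-way factorial
    ANOVA screening with Type II sums of squares, cross-species mature
    miRNA conservation by affine-gap global alignment, dose- and
    time-response marker regression with single-marker ROC analysis, and
    a wrapper biomarker-panel search (random-forest candidate ranking,
    exhaustive 2-10 feature subpanel enumeration, logistic panel models
    scored by repeated-split and k-fold cross-validated AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    edgeR,
    Biostrings,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
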