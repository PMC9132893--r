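Package: panelscan
Title: Genetic and Pharmacogenomic Landscape Analysis of Curated Gene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for pan-cancer characterization of a curated
    gene panel (shipped example: the 28 transient-receptor potential channel
    genes in six families). Covers somatic mutation and copy-number landscape
    statistics including a binomial tail test for mutation enrichment in
    transmembrane regions with an enrichment ratio; tumor-versus-normal
    differential expression with rank-sum tests and BH adjustment;
    tissue-specificity classification; alteration-status clinical comparisons,
    log-rank tests, maximally selected survival cutpoints and univariate Cox
    hazard ratios; preranked gene set enrichment analysis on co-expression
    rankings with a set-permutation null; and drug-sensitivity (IC50)
    correlation screens with KNN imputation of missing values. A synthetic
    cohort generator reproduces the statistical structure of the real inputs
    so every stage is exercisable and testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite,
    withr
Config/testthat/edition: 3
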