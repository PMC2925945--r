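Package: methmark
Title: Two-Stage DNA Methylation Biomarker Discovery for Bladder Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for discovering and validating CpG methylation
    markers of invasive bladder cancer from GoldenGate-style average-beta
    arrays. Provides sample and locus quality-control filters with autosomal
    restriction; three parallel locus-selection procedures (locus-wise
    quasi-binomial generalized linear models with Storey q-value false
    discovery rate control, random-forest classification with out-of-bag
    permutation testing and percent-change-in-MSE importance, and recursively
    partitioned beta-mixture models with a class-versus-rest AUC ranking); a
    cross-series intersection rule for candidate loci; pyrosequencing
    validation statistics (Spearman site correlations, Kruskal-Wallis and
    protected Wilcoxon tests, median dichotomization, odds ratios and
    multivariable logistic regression, the Pfaffl fold change); and a
    synthetic-data generator emulating beta-distributed methylation cohorts so
    the full pipeline runs and is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
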