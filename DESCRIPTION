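Package: atrophynet
Title: Graph-Based Subtyping of Disease Cohorts from Cortical Atrophy Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters patients into anatomical disease subtypes from cortical
    thickness data. Thickness is standardized to z-score atrophy patterns
    against a cognitively normal reference group, patients are connected by
    the Pearson correlation of their atrophy patterns, and subtypes are
    extracted by resolution-parameterized Louvain modularity maximization
    with majority-vote consensus over many stochastic runs. Includes a
    synthetic cohort generator with planted subtype templates, permutation
    tests for the similarity structure and for cross-cohort subtype
    consistency, a leave-subset-out reproducibility statistic, hierarchical
    clustering comparators, and ROI-level hallmark analysis via
    permutation-based ANCOVA with Benjamini-Hochberg FDR control.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    igraph,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
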