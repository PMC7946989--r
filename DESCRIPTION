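Package: rulenet
Title: Interpretable Rule-Based Models and Co-Predictive Networks for
    Multi-Cohort Transcriptomics
Version: 0.1.0
Authors@R: person("rulenet", "developers", email = "rulenet@example.org",
    role = c("aut", "cre"))
Description: Rough-set rule induction for case-control gene expression
    cohorts: equal-frequency discretization into decision tables, Monte
    Carlo feature selection with critical-angle and model-quality
    thresholding, Johnson-reduct rule learning with cross-validated
    standard voting, merging of rule models across cohorts, co-predictive
    (feature, level) networks with connection weights, and subgroup
    dissimilarity testing by betweenness-centrality distance with a
    balanced permutation null. Includes a synthetic multi-cohort data
    generator with planted co-regulated gene pairs and graded subtype
    effects so the full pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
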