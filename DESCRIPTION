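Package: mpnet
Title: Module-to-Phenotype Network Analysis for Transcriptomic Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds module-to-phenotype networks (MPN) from brain
    transcriptomic cohorts: weighted co-expression module detection
    (Pearson similarity, soft-thresholded adjacency, topological overlap,
    tree cutting, module eigengenes, covariate-adjusted module-trait
    statistics), score-based Gaussian Bayesian-network structure learning
    with restarts and model averaging over module eigengenes and
    Alzheimer's disease phenotypes (MMSE, Braak stage, tangle counts,
    cognitive reserve), Markov-blanket-based module prioritization, and
    edge-percolated-component centrality for hub-gene ranking within a
    prioritized module. Includes a synthetic-cohort generator with planted
    modules and module-driven phenotypes, downstream group-contrast
    statistics with Bonferroni adjustment, eigengene projection into
    external cohorts, and a reproducible pipeline driver with TSV/GraphML
    export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
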