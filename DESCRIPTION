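Package: spotcount
Title: Distributional Characterization of Spatial Transcriptomics Count Data
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Per-gene fitting and comparison of Poisson, negative binomial,
    zero-inflated Poisson and zero-inflated negative binomial models for
    gene-by-location count matrices, with sequencing-depth offsets and optional
    cell-type-composition covariates. Provides four likelihood ratio tests for
    zero inflation and overdispersion with Bonferroni correction, AIC model
    selection, a moment-based GEE fallback for non-convergent negative binomial
    fits, cross-gene mean-variance and mean-zero-proportion trend fitting by
    Gauss-Newton least squares, location clustering (normalization, highly
    variable genes, PCA, shared-nearest-neighbor Louvain) with cluster-specific
    re-analysis and before/after preference ratios, cell-type-conditional
    re-analysis, and a seeded synthetic-data generator with known ground truth
    for all of the above.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
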