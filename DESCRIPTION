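Package: ctapr
Title: Cell-Type Abundance Phenotypes for Multi-Sample Single-Cell Cohorts
Version: 0.1.0
Authors@R: person("CTAP", "Maintainers", email = "maintainers@ctapr.dev",
    role = c("aut", "cre"))
Description: Stratifies multi-sample single-cell cohorts into cell-type
    abundance phenotypes (CTAPs) by bootstrap-stable hierarchical clustering
    of per-sample lineage proportions, associates single-cell neighbourhoods
    with the resulting phenotypes via a covarying-neighbourhood permutation
    test, transfers CTAP labels to flow-cytometry compositions and bulk
    RNA-seq through signature deconvolution, and provides the downstream
    association statistics (variance explained, expression-matched risk-gene
    enrichment, treatment-response odds ratios, repeat-biopsy stability).
    Ships a synthetic-cohort generator so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    FNN,
    igraph,
    jsonlite,
    cluster,
    methods,
    stats,
    tools,
    utils
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
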