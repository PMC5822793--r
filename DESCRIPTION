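Package: netscore
Title: Coexpression Network Modules and a Convolutional Survival Score
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted gene coexpression networks (Pearson correlation,
    soft-threshold adjacency, topological overlap, average-linkage clustering,
    dynamic tree cut), screens module eigengenes for association with overall
    survival by Cox regression, selects representative hub genes by module
    membership, and trains a small convolutional neural network with a Cox
    partial-likelihood loss to produce a scalar prognostic risk score
    (NetScore). Includes a synthetic multi-cohort generator with planted
    module structure and planted proportional-hazards effects, survival
    analytics (Kaplan-Meier, log-rank, Harrell's C-index, median
    dichotomization, subgroup and multivariate Cox tables), and an
    end-to-end, seed-reproducible pipeline with TSV reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    igraph,
    yaml,
    optparse
Config/testthat/edition: 3
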