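Package: irnet
Title: Network-Based Key Driver Discovery for Insulin Resistance Expression Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for discovering key driver genes of insulin
    resistance from multi-clone iPSC RNA-seq cohorts. Implements count
    filtering, TMM/log-CPM normalization and mixed fixed/shrunken covariate
    residualization (all-samples and average-per-patient streams), moderated
    differential expression, weighted co-expression networks with topological
    overlap module detection and permutation background, breadth-first seed
    expansion over a prior interaction network, Bayesian-network structure
    learning with cis-eQTL root constraints and additive-noise edge
    orientation, key driver analysis with Fisher neighborhood enrichment and
    inverse-path-length ranking scores, and layer-wise in-silico perturbation
    validation. Ships a synthetic cohort generator with planted ground truth
    (modules, causal DAG, key drivers, covariate effects, perturbation
    schedule) so every stage can be benchmarked without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    limma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr,
    optparse
Config/testthat/edition: 3
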