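Package: protnet
Title: Weighted Protein Co-Expression Network Analysis for Two-Batch TMT
    Proteomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for tandem-mass-tag (TMT)
    proteomic abundance matrices acquired in two batches, as in a 2x2
    genotype-by-age mouse brain design. Provides sample network
    connectivity quality control, per-protein one-way ANOVA with Tukey
    HSD post-hoc tests and volcano classification, weighted
    co-expression network construction (biweight midcorrelation,
    soft-threshold adjacency, topological overlap, dynamic hybrid tree
    cut, module eigenproteins, kME, module merging and reassignment),
    post-hoc mapping of batch-missing proteins into modules,
    module-trait correlation, hypergeometric cell-type and Z-score
    ontology enrichment with Benjamini-Hochberg correction and
    kappa-based term clustering, and a synthetic-data generator with
    planted ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
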