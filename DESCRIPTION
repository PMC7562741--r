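Package: immunoprofiler
Title: Transcriptomic Immunoprofiling of Inflamed Tissue
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A multi-stage immunoprofiling workflow for small-cohort bulk
    transcriptomics of inflamed tissue. Provides empirical-Bayes moderated
    differential expression with Benjamini-Hochberg control, Fisher-exact
    enrichment of gene lists against cell-type and functional taxonomies with
    odds-ratio confidence intervals, weighted co-expression network module
    discovery (soft-threshold adjacency, topological overlap, eigengenes,
    module-trait correlation and QC), per-sample gene-set scoring by a
    weighted Kolmogorov-Smirnov random walk with Welch/Hedges group
    contrasts, iterative Spearman co-expression refinement of literature
    signatures, and connectivity-score drug-target summarization. A synthetic
    data generator with recorded ground truth emulates the statistical
    structure each stage assumes, so the whole pipeline is testable without
    access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
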