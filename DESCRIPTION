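Package: scDropletKit
Title: Droplet Single-Cell RNA-Seq Clustering Pipeline and Technical QC
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis for droplet-based single-cell RNA-seq
    starting from a UMI count matrix: cell and gene quality filtering,
    library-size normalization, cell-cycle scoring and covariate
    regression, variable-gene selection, principal component analysis,
    shared-nearest-neighbor Louvain clustering with a random-forest
    out-of-bag cluster-merge validation step, Wilcoxon marker detection,
    pseudobulk (in silico average) comparisons and an immunoglobulin
    kappa/lambda plasma-cell ratio. Also provides droplet technical QC:
    Poisson bead/cell encapsulation statistics, two-species (barnyard)
    doublet estimation, and ERCC spike-in sensitivity and accuracy
    metrics. A synthetic-data module generates multi-run UMI matrices
    with planted subpopulations, cell-cycle modules and batch effects so
    the whole pipeline is testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    igraph,
    ranger,
    Rtsne,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
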