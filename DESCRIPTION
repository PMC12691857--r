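Package: cnmnet
Title: Multilayer Network Integration and Co-Expression Analysis for
    Centronuclear Myopathy Multi-Omics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse multi-omics data from centronuclear myopathy
    (CNM) mouse models with two complementary network approaches. The first
    arm is a weighted gene co-expression analysis: count filtering,
    median-of-ratios normalization, soft-power adjacency, topological
    overlap, module detection by dynamic dendrogram cutting with eigengene
    merging, module-trait correlation with Bonferroni adjustment, and
    classification of modules as beneficial or pathogenic from the signs of
    their significant trait correlations. The second arm builds
    multiplex-heterogeneous multilayer networks (genes, metabolites,
    reactions, phenotypes, tissues linked by bipartite networks) and
    explores them by random walk with restart, including a resampling null
    that detects and removes nonspecific hub nodes, and joint-seed
    prioritization of genes and metabolites. Synthetic-data generators with
    known ground truth support validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    igraph,
    jsonlite,
    DESeq2
Config/testthat/edition: 3
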