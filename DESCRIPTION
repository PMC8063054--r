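Package: microgliaID
Title: Transcriptome Identity Validation for Induced Microglia-Like Cells
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Validates the transcriptome identity of monocyte-derived induced
    microglia-like (iMG) cells against brain-resident microglia references.
    Provides a negative-binomial count simulator with planted cell-type
    structure and batch effects, a normalization chain (median-of-ratios size
    factors, FPKM, variance-stabilizing transform, batch-effect removal,
    unit rescaling), classical multidimensional scaling and hierarchical
    clustering with cluster-recovery metrics, a negative-binomial Wald
    differential-expression test, a cross-dataset fold-change consistency
    score with the associated signature-gene filtering cascade, presence-based
    three-set Venn partitioning of expressed genes, and 2^-ddCT relative
    quantification for qPCR readouts. An end-to-end pipeline runs every stage
    on simulated or user-supplied count matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    limma,
    Matrix,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    edgeR
Config/testthat/edition: 3
biocViews: Transcriptomics, RNASeq, GeneExpression, Clustering,
    DifferentialExpression, Normalization
RoxygenNote: 7.3.3
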