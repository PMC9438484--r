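Package: seedvar
Title: Single-Seed RNA-Seq Variability Analysis for Dormancy Induction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-seed RNA-seq of secondary dormancy
    induction: demultiplexing and deduplication of split-UMI paired reads into a
    seed-by-gene UMI count matrix, quality filters including removal of genes
    correlated with unspecific (intergenic) background, regularized
    negative-binomial normalization with technical covariates yielding clipped
    Pearson residuals, pool-split-calibrated highly variable gene detection,
    highly-connected-subgraph co-expression module discovery, composite
    germination-competence signature scoring, and Wilcoxon rank-sum differential
    expression between seed sub-pools and sequential time points. Includes a
    synthetic-data generator (count-level and FASTQ-level) with ground truth so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    igraph,
    cluster,
    Biostrings,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
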