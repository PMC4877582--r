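Package: lnckit
Title: lncRNA Catalog Construction, Differential Expression and Target
    Prediction for Grouped RNA-Seq Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a long noncoding RNA (lncRNA) catalog from assembled
    transcript models: filters candidates by length, exon count, abundance,
    protein-coding overlap and coding potential; splits known from novel
    transcripts by intron-chain comparison against a reference lncRNA
    annotation; and classifies each lncRNA as intergenic (lincRNA), intronic
    or antisense relative to protein-coding genes. Quantifies abundance as
    FPKM, calls differential expression between sample groups with a
    pooled-variance t-test and Benjamini-Hochberg adjustment, clusters
    samples by correlation distance, predicts cis (within a genomic window)
    and trans (coexpressed, distant) protein-coding targets of lncRNAs,
    compares neighbor-pair correlation classes against a random-pair null,
    and scores gene-set over-representation with the hypergeometric test.
    A seeded simulator generates toy genomes, grouped expression with
    planted effects, and gene sets with exported ground truth so the whole
    workflow is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    mclust,
    GenomicRanges,
    rtracklayer
Config/testthat/edition: 3
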