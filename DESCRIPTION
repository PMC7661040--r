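Package: methclock
Title: Epigenetic Clocks and Co-Methylation Networks for Rodent RRBS Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and transferring DNA-methylation age
    (DNAmAge) clocks from reduced representation bisulfite sequencing
    (RRBS) call tables. Assembles coverage-filtered CpG beta matrices,
    imputes missing values with a k-nearest-neighbour sliding genomic
    window, trains unsupervised principal-component clocks and sparse
    elastic-net clocks with month rescaling, maps CpG coordinates across
    genome assemblies through UCSC chain files, detects consensus
    co-methylation modules (signed topological overlap, dynamic tree cut,
    kME pruning), fits covariate-adjusted aging association models
    (physical function, cell composition, caloric restriction), annotates
    CpGs by genomic context, and computes region-set enrichment. Ships a
    seed-reproducible two-species synthetic cohort generator that emulates
    the statistical structure every stage assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    glmnet,
    data.table,
    jsonlite,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Epigenetics, DNAMethylation, Sequencing, Network, Aging
RoxygenNote: 7.3.3
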