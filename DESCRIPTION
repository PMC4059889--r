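Package: chipcooc
Title: ChIP-Seq Co-Occupancy Clustering and Gene-Target Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for multi-factor ChIP-seq co-occupancy
    analysis: replicate-consensus peak filtering with MACS-style score and
    FDR thresholds, input normalization of binned coverage using signal
    extraction scaling (SES), region-anchored signal matrices, rank-transform
    Ward hierarchical clustering of binding patterns, genomic and enhancer
    annotation with GREAT-style basal-plus-extension regulatory domains,
    promoter-proximal/distal gene-target classification, and cross-tabulation
    of target classes against knockdown differential expression. Includes a
    synthetic-data generator that plants known co-occupancy clusters, target
    genes and knockdown effects so every stage can be validated against
    ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
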