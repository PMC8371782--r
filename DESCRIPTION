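Package: chipnorm
Title: Inter-Sample Normalization of ChIP-Seq Density Tracks Anchored on
    Transcriptionally Constant Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Normalizes ChIP-seq (and ATAC-seq/DNase) signal density tracks
    across samples or conditions without spike-in chromatin.  The method
    assumes that genes whose expression varies least across samples carry,
    on average, the same true signal in their regulatory regions.  Those
    "constant" genes are selected per expression stratum from an RNA-seq or
    microarray matrix, a scale-regions signal matrix is built over them from
    each bigWig track, and either an affine regression against a reference
    sample or a group-wise quantile normalization with a monotone spline map
    is learned and applied genome-wide.  Diagnostics include zone-based
    percent differences of average TSS profiles before and after
    normalization and expression-stratified TSS meta-profiles for antibody
    specificity checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    ggplot2,
    rlang,
    stats,
    utils,
    grDevices,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
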