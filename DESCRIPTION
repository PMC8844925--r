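Package: capregulon
Title: TSS Calling, Operon Mapping and Regulon Integration for Bacterial
    5'-End Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-nucleotide transcription start site (TSS) calling from
    Cappable-seq style 5'-end read tracks (weighted multi-mapper counting,
    relative read score normalization, thresholding and clustering), operon
    prediction from intergenic distance, developmental expression profiling
    of count matrices (median-of-ratios normalization, log2 fold changes
    against a reference time point, four-way cluster classification), and
    integration with transcription-factor ChIP-seq peak summits and IUPAC
    consensus binding sites to nominate directly regulated genes. Includes a
    seeded synthetic-data generator with planted ground truth that emulates a
    small bacterial chromosome with two-replicate 5'-end tracks, a five
    time-point count matrix and planted ChIP peaks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    GenomeInfoDb,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
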