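Package: clashr
Title: Detection, Folding and Annotation of Chimeric Reads from CLASH
    Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained pipeline for calling RNA-RNA interactions from
    CLASH (crosslinking, ligation and sequencing of hybrids) and related
    high-throughput sequencing data. Reads are demultiplexed by 5' barcode,
    adapter- and quality-trimmed, collapsed into unique sequences, and mapped
    against a transcript database with a built-in seed-and-extend local
    aligner (or with imported blast-tabular alignments). Reads carrying two
    non-contiguous matches are called as chimeras, the two fragments are
    folded as an intermolecular RNA-RNA duplex under a nearest-neighbor
    energy model, and overlapping chimeras are merged into supported
    interactions. Includes readers and writers for the hyb and viennad
    formats, converters to GFF3 and genomic coordinates, and a synthetic
    CLASH library generator for end-to-end benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    data.table,
    methods,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
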