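Package: isopipe
Title: Long-Read Isoform Sequencing Transcriptome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-guided analysis of long cDNA (Iso-Seq style) reads:
    iterative alignment and error correction against a reference genome with
    splice-junction masking, position-weight-matrix filtering of splice
    junctions, strand assignment from poly(A) tails, collapsing of reads into
    unique splice isoforms by intron-chain identity, splice-graph
    classification of alternative-splicing events, greedy clustering and
    classification of alternative polyadenylation sites, novel-gene and
    long non-coding RNA candidate calling, and a synthetic-data generator
    that emits full truth tables so every stage can be validated without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
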