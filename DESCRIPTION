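Package: hcorrect
Title: Hybrid Error Correction of Long Reads by Homopolymer-Compressed
    Short-Read Consensus
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Corrects high-error long reads (such as PacBio SMRT transcriptome
    reads, with error rates near 15 percent dominated by insertions and
    deletions at homopolymers) using accurate short reads. Both read sets are
    homopolymer-compressed, short reads are aligned to the compressed long
    reads with an external aligner, and a per-column voting scheme with a
    coverage-frequency threshold (SCF) resolves mismatches, insertions and
    deletions -- including homopolymer runs of length one -- in a single pass.
    Includes quality control of short reads, sequence-identity evaluation of
    corrected reads, and a seeded simulator of transcripts, noisy long reads
    and accurate short reads for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    S4Vectors,
    data.table,
    stats,
    utils,
    withr
Suggests:
    BiocGenerics,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
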