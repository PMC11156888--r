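Package: breaktag
Title: Discovery and Quantification of dsODN-Tagged CRISPR-Cas9 Double-Strand Breaks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nominates CRISPR-Cas9 off-target cleavage sites from sequencing
    libraries in which a short double-stranded oligodeoxynucleotide (dsODN) tag
    has been captured into double-strand breaks by end joining. The workflow
    demultiplexes barcoded, UMI-tagged paired-end reads, detects the dsODN tag
    and its orientation, aligns the flanking genomic fragments with a built-in
    seed-and-extend aligner (or ingests external SAM alignments), consolidates
    UMI-deduplicated tag-genome junctions into cleavage sites, annotates each
    site with its best protospacer+PAM match under a combined mismatch budget,
    classifies replicate confidence, and computes the off-index (total
    off-target over on-target reads). A companion length-window classifier
    quantifies dsODN insertion outcomes (single, double, other) in targeted
    amplicon data, and a fully deterministic simulator generates discovery
    libraries and amplicon pools with planted ground truth so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    S4Vectors,
    data.table,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
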