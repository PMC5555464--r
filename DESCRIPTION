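Package: spliceform
Title: Transcript Structure Annotation: Alternative Promoters, First Exons,
    Splice Events and Their Coding Consequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the transcript repertoire of a gene locus
    from mapped transcript 5'-end evidence and alternative transcript models.
    Calls putative transcription start sites (TSSs), clusters them into
    putative alternative promoters with sharp/broad shape and TATA-box
    classification, classifies alternative first exons (mutually exclusive,
    5'-extension, intron-retaining), enumerates splice events between
    isoforms (exon skipping, alternative donors/acceptors, NAGNAG tandem
    acceptors, mutually exclusive exon pairs, intron retention), and computes
    the protein-level consequence of each event: in-frame deletions, junction
    substitutions, frameshifts with premature termination codons and
    nonsense-mediated-decay flags, and N-terminal truncation bookkeeping.
    Includes a seeded simulator of synthetic gene loci with ground-truth
    annotations for every feature class.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
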