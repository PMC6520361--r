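Package: splicetx
Title: Splice-Site Mutation Classification and Aberrant Transcript Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for the transcript-level analysis of splice-site mutations.
    Parses and classifies intronic and splice-region mutations given in HGVS
    coding-DNA (c.) notation against a transcript model, detects aberrant
    transcript variants (exon skipping, cryptic splice-site usage, intron
    retention) in aligned RNA-seq reads using read-count and coverage filters,
    estimates per-sample relative expression of canonical and aberrant
    transcript variants, and predicts protein-level consequences such as
    reading-frame disturbance, premature termination codons and truncation,
    including recognition of named isoforms (e.g. the truncated TP53 isoform
    p53psi). A deterministic simulator of gene models and spliced alignments
    with known transcript mixtures supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
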