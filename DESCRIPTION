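Package: evsmallrna
Title: Small RNA Profiling of Plasma Extracellular-Vesicle Sequencing Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing, annotation, quantification and differential-expression
    analysis for single-end small-RNA sequencing libraries from plasma
    extracellular vesicles (EVs). Reads are classified into six rejection
    categories (3' adapter missing, empty insert, 5' adapter contamination,
    inferior quality, under 17 nt, homopolymer repeats) and clean 17-45 nt
    inserts are collapsed to unique tags, matched against a catalog of mature
    small non-coding RNAs (miRNA, YRNA, tRNA, rRNA, snRNA, snoRNA, piRNA) with
    a bounded-mismatch matcher, and summarized as reads-per-million (RPM)
    composition, length-distribution and chromosome-abundance tables. miRNA
    tags are confirmed against mature references, isomiRs sharing a 5' end are
    merged, and features between two unreplicated pooled libraries are tested
    with a conditional negative-binomial exact test with Benjamini-Hochberg
    correction. A synthetic-library generator with full ground truth makes
    every stage verifiable, and a 2^-deltaCt calculator supports qRT-PCR
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    rtracklayer,
    S4Vectors,
    stats,
    utils
Suggests:
    edgeR,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
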