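Package: ribocall
Title: Noise-Tolerant Prediction of Translated ORFs from Ribosome Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts translated open reading frames (ORFs) from ribosome
    protected footprint (RPF) alignments, tolerating footprints with poor
    triplet periodicity. Footprint read lengths are screened with a
    multitaper harmonic F-test on start-codon metagene profiles, P-site
    offsets are extracted probabilistically per read length, and the
    evidence from in-frame footprint occupancy is balanced against
    genome-wide codon usage through an entropy weight before four
    frame-comparison t-tests are combined with a weighted chi-square
    statistic. Called ORFs are classified into eleven positional and
    biotype categories (annotated, truncated, extended, uORF, ouORF, dORF,
    odORF, ncsORF, internal, teORF, pORF). A synthetic data generator
    produces toy genomes, annotation and aligned footprints, including a
    read-trimming noise protocol, so the whole pipeline can be exercised
    without external data.
License: MIT
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
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
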