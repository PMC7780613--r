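Package: sgcompact
Title: Simulation of SCRaMbLE-Based Compaction of Synthetic Yeast Chromosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models iterative SCRaMbLE-based genome compaction (SGC) of a
    synthetic yeast chromosome arm in silico. Provides a loxPsym-unit (LU)
    chromosome model with GFF3/TSV/FASTA input and output, a Cre/loxPsym
    recombination event simulator over cell populations, viability and
    5-fluoroorotic acid counterselection logic with episomal essential-gene
    array (eArray) complementation, Hi-C contact-matrix balancing and
    insulation-score detection of chromosomal interacting domains (CIDs)
    used as recombination proximity weights, LU-profile reconstruction with
    in-silico PCRtag screening, and round-by-round compaction bookkeeping.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
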