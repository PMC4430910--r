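Package: nrsescan
Title: Genome-Wide Screening and Regulatory Association Analysis of
    NRSE/RE1 Transcription-Factor Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for genome-wide screens of the neuron-restrictive
    silencer element (NRSE, also called RE1), the DNA motif bound by the
    transcriptional repressor REST/NRSF. Implements exact scanning of a
    degenerate IUPAC consensus (including half-site and bipartite
    variants) over both strands of a genome, annotation of motif hits by
    distance to gene models parsed from GTF, permutation cataloguing and
    cross-species motif-set comparison, position frequency matrices with
    information content and IUPAC consensus calls, a gap-aware
    within-chromosome interval-shuffling null model with chi-square
    association tests against non-coding RNA gene classes, UCSC chain
    alignment parsing for cross-species motif co-occurrence, and a
    synthetic-data generator with planted ground truth for end-to-end
    validation.
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
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
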