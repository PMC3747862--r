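Package: lasagna
Title: Length-Aware Alignment of Transcription Factor Binding Sites and
    Pair-Aware PSSM Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Progressive, gapless, length-aware multiple alignment of
    variable-length transcription factor binding sites (the LASAGNA
    algorithm), position-specific scoring matrices extended with
    dinucleotide pair scores up to a scope K, a ChIP-seq variant with
    peak clipping, adaptive information-content trimming and iterative
    refinement, binding-site scanning with empirical p-values, and a
    cross-validation framework that evaluates alignments by the search
    performance of the PSSMs they induce. Includes seeded synthetic-data
    generators (planted-motif site sets and peak sets with ground truth)
    used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    optparse,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
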