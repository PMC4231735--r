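Package: dropem
Title: Reverse-Transcription Drop-Off Analysis and Two-Channel Poisson EM
    for RNA Structure Probing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for chemical RNA structure probing read-out by
    reverse-transcription (RT) drop-off. Converts paired-end alignments of
    randomly primed cDNA against a single transcript into per-nucleotide
    stop-count and coverage tracks, computes RT drop-off rates and
    normalized, capped chemical (SHAPE/DMS) reactivities, and calls
    chemically modified nucleotides with a two-channel Poisson
    expectation-maximization mixture model that contrasts a treated channel
    against a solvent control. Includes a generative simulator with known
    modification ground truth and utilities to summarize and compare
    modification calls across samples.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    Rsamtools,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
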