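Package: hmmdemux
Title: Profile Hidden Markov Model Extraction, Demultiplexing and
    Filtering of Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Declares the architecture of raw sequencing reads (adapters,
    sample barcodes, spacers, unique molecular identifiers and the mappable
    insert) as an ordered set of blocks, compiles the declaration into a
    global profile hidden Markov model, and uses forward/backward scoring
    with optimal-accuracy posterior decoding to label, demultiplex and trim
    reads with a phred-scaled extraction quality. Includes automatic
    threshold calibration by emission from the model, architecture
    auto-detection against a library of candidates, bit-parallel approximate
    matching against contaminant references, a trinucleotide low-complexity
    filter, and a ground-truth read simulator for recall/precision
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
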