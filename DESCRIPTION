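Package: tnfusion
Title: Design and Simulation of Markerless Transposon-Delivered Fluorescent
    Fusions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Toolkit for designing and analysing markerless mariner (Himar)
    transposon constructs that create in-frame internal fluorescent protein
    fusions. Enumerates and classifies TA target sites by codon phase,
    validates the frame arithmetic of reading-frame-preserving transposon
    architectures, constructs insertions with TA target-site duplication,
    predicts the resulting fusion proteins, maps short junction tags back to
    insertion sites, builds split-fluorophore constructs for bimolecular
    fluorescence complementation, and simulates FACS-based gene-trap
    enrichment of on-target fusions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    methods,
    rtracklayer,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
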