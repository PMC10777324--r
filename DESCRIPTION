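Package: nmrkit
Title: Headless 1D NMR Processing, Multiplet Analysis and Teaching Exercises
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A scriptable toolkit for one-dimensional NMR data: import and
    export of JCAMP-DX files (AFFN and SQZ/DIF/DUP compressed data, NTUPLES
    FIDs) and Bruker raw-data directories, a reversible filter-chain
    processing pipeline (apodization, zero-filling, Fourier transform,
    manual and automatic phase correction, baseline correction,
    referencing), signal analysis with noise-aware peak picking,
    integration and automatic multiplet analysis of possibly overlapping
    resonances, MDL molfile handling with hydrogen-equivalence (topicity)
    detection and canonical structure comparison, JSON workspace
    serialization, and a builder and grader for teaching-exercise sets.
    A first-order spin-system simulator generates ground-truth spectra for
    testing and for fabricating exercise content.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
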