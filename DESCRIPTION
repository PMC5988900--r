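Package: sRNAcycle
Title: Cell-Cycle Regulatory Analysis of Bacterial Non-Coding RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Links bacterial cell-cycle master regulators (DnaA, CtrA,
    GcrA and the CcrM methyltransferase) to non-coding RNAs in
    Caulobacter crescentus. Provides position-weight-matrix scanning of
    promoter regions with an information-content score and a relative
    retention threshold, IUPAC degenerate motif matching (GANTC
    methylation sites), classification of synchrony expression time
    courses into cell-cycle phases, integration of small-RNA target
    predictions from three tools under a confirmation rule, assembly and
    export of the regulator-to-ncRNA-to-target network, and a seeded
    synthetic-data generator so every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
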