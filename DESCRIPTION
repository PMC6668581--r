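Package: BTScan
Title: Prediction and Benchmarking of Bipartite Targeting Presequences in
    Organisms with Complex Plastids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to train species-specific bit-score-weighted matrices of
    amino acid positions surrounding signal-peptide cleavage sites, scan
    protein N-termini with a sliding-window transit-peptide scorer, call
    consensus cleavage sites across multiple predictors, and calibrate
    per-species classification thresholds by sensitivity/precision
    analysis. Includes a position-weight-matrix signal-peptide predictor,
    parsers for external localization-predictor output tables, and a seeded
    generator of labelled synthetic presequence fixtures for benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'adapters.R'
    'benchmark.R'
    'bitscore.R'
    'cleavage.R'
    'scanner.R'
    'seqio.R'
    'synthetic.R'
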