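Package: rbh3tools
Title: rBH3 Motif Scanning, NMR Chemical-Shift Perturbation Mapping and
    Fluorescence-Polarization Binding Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise reverse-BH3 (rBH3) mediated
    protein-protein interactions such as the one between the first RNA
    recognition motif (RRM1) of PTBP1 and the prosurvival Bcl-2 family
    protein MCL1. Provides a position-offset register scanner for BH3 and
    rBH3 motifs in protein sequences, per-residue 15N-HSQC chemical-shift
    perturbation (CSP) analysis with mutual-nearest peak matching,
    mean + 1 SD significance calling and triplicate consensus, structure
    mapping of CSPs onto PDB B-factors, four-parameter logistic fitting of
    direct and competitive fluorescence-polarization titrations, and a
    fully seeded synthetic-data generator for ground-truthed validation of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
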