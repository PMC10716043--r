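Package: dnagel
Title: Design and Viscoelastic Analysis of DNA-Crosslinked Hydrogels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing combinatorial DNA splint crosslinker
    libraries and analysing the hydrogels they form. Expands degenerate
    (ambiguous-base) overlap domains into explicit splint libraries,
    predicts duplex stability and pairing selectivity from unified
    nearest-neighbour thermodynamics (Boltzmann-weighted minimum-free-energy
    matrices, melting temperatures, blocking-strand occupancy), simulates
    the suppression of elastically ineffective intramolecular crosslinks as
    a function of library complexity, inverts the affine rubber-elasticity
    network model to estimate crosslinking efficiency, and extracts Maxwell
    stress-relaxation times, gel melting points, phase angles and
    self-healing recovery from rheometer traces. Includes seeded synthetic
    generators for every input so the full pipeline is testable without
    instrument data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
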