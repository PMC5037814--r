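Package: casqtools
Title: Post-Translational Modification Analysis of Calsequestrin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing glycosylation and phosphorylation of
    the sarcoplasmic-reticulum calcium-buffer protein calsequestrin from
    MALDI-TOF peptide mass spectra, and for comparing its crystal
    structures. Implements in-silico cyanogen bromide (CNBr) digestion
    with homoserine-lactone chemistry, glycoform/phosphoform composition
    assignment of peak lists by expected-mass matching with
    signal-to-noise filtering, mass-ladder detection, Kabsch least-squares
    superposition and r.m.s.d. matrices, normalized B-factor profiles,
    crystallographic symmetry expansion with ion counting, pairwise
    percent identity/similarity matrices, and synthetic-data generators
    that make every pipeline stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
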