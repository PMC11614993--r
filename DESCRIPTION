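Package: iminoT1
Title: Selective T1 Relaxation Analysis and Acquisition Planning for In-Cell NMR of Nucleic Acids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for one-dimensional imino-proton
    selective inversion-recovery NMR of nucleic acids inside living cells.
    Generates synthetic free induction decays with in-cell-like noise, drift
    and delay schedules; processes them with exponential apodization,
    truncation and linear prediction; extracts peak intensities at frozen
    chemical shifts with a signal-to-noise based error model; fits the
    mono-exponential recovery law individually or globally with a shared
    relaxation time and corrects for sample deterioration; plans SOFAST-style
    recovery delays that maximise sensitivity per unit time under instrument
    constraints; and provides the cell-level quantification arithmetic
    (sphere volumes, nuclear/cytoplasmic partition, interstitial-medium
    fraction, sequential-wash dilution, gel standard-curve concentration).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
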