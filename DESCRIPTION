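Package: ecquant
Title: Quantification of Enterochromaffin-Cell Stimulus Responses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Signal-analysis pipeline for single-cell physiology of human
    enterochromaffin (EC) cells: ratiometric Ca2+ (Fura2 340/380) and
    cAMP-FRET (CFP/YFP) trace quantification with a z-score responder
    classifier and positive-control inclusion gating; membrane-capacitance
    exocytosis analysis (immediately and readily releasable pool
    decomposition, cell quality-control taxonomy, potentiation protocol);
    action-potential detection and waveform metrics; and secretion-plate
    normalization with fold-change statistics. Ships seeded synthetic-data
    generators emulating the acquisition protocols so every estimator is
    verifiable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    multcomp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
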