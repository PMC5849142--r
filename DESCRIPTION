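Package: hsoligo
Title: Sequence Analysis, Mass Spectrometry and NMR Shift Prediction for
    Heparan Sulfate Oligosaccharides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for structurally defined heparan sulfate (HS) and heparin
    oligosaccharides of the kind produced by chemoenzymatic synthesis. Provides
    a plain-text sequence grammar and validator for the alternating
    uronic-acid/glucosamine alphabet (GlcA, IdoA2S, GlcNS3S6S, ...), elemental
    composition and average/monoisotopic mass calculation with negative-mode
    ESI charge-state ladders, a context-dependent anomeric 1H/13C chemical
    shift predictor with J-coupling classes, cost-minimizing assignment of
    observed anomeric peak lists to candidate sequences, a rule-based planner
    for chemoenzymatic synthesis routes (pmHS2 elongation, NST, C5-epimerase,
    2-OST/6-OST/3-OST-1 sulfotransferases), and simulation of noisy anomeric
    peak lists for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
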