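Package: cavesleepr
Title: Sleep Scoring, Expression and Cell Quantification for Cavefish Behavioral Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores sleep from locomotor tracking exports of Astyanax mexicanus
    (surface and Pachon cave morphs) using the immobility-bout definition of
    sleep (immobility of 60 s and greater), derives per-fish sleep-architecture
    metrics and zeitgeber-time profiles, quantifies relative gene expression
    from qPCR Ct tables (delta-delta-Ct with reference-gene normalization and
    inter-run calibration), quantifies fluorescent somata from confocal
    z-stacks, and runs the factorial statistics layer (two-group tests,
    genotype-by-treatment ANOVA with Holm-Sidak step-down correction).
    Includes a two-state semi-Markov activity simulator and generators for
    qPCR plates and image stacks with known ground truth, so every stage can
    be validated by parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tiff,
    car,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
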