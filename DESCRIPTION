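Package: ribohcs
Title: High-Content RNAi Screen Analysis for Ribosome Biogenesis Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis pipeline for microscopy-based RNAi screens
    of ribosome biogenesis factors. Segments nuclei from a DNA-stain channel,
    extracts a fixed 30-feature vector per cell, classifies cells into
    localization phenotypes with a supervised model, aggregates per-well hit
    rates, normalizes them between plate negative and positive controls, calls
    candidate and high-confidence hit targets, and scores nuclear defects along
    the maturation pathway (nucleolar versus nucleoplasmic). Includes a
    seeded synthetic-screen generator at two fidelity levels (rendered
    two-channel images and direct per-cell feature tables) with exported
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    MASS,
    EBImage,
    ranger,
    pROC,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
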