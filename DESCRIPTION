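Package: aerorate
Title: Drone-Based Remote Photoplethysmography Heart-Rate Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A processing pipeline for single-value heart-rate assessment
    from drone video via remote photoplethysmography (rPPG). Includes
    gimbal-aware digital image derotation, face-aware adaptive exposure
    control, facial region-of-interest colour-signal extraction,
    least-squares de-noising against flight-sensor and tracking nuisance
    signals, CHROM and POS pulse extraction, spectral peak gating by a
    band-power signal-to-noise criterion, and median-spectrum fusion into
    one heart rate. A synthetic flight-scene simulator with full ground
    truth makes every stage testable without field recordings, and an
    evaluation module computes RMSE, Bland-Altman agreement and
    motion/exposure subset splits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    MASS,
    withr
Config/testthat/edition: 3
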