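Package: plasmafp
Title: Plasma Metabolic Fingerprinting by LC-MS with PLS-DA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for untargeted LC-MS plasma metabolic
    fingerprinting of three-group case/control cohorts (controls, small
    and large abdominal aortic aneurysm). Provides a synthetic cohort
    generator with known ground truth, peak-list alignment, presence
    filtering, log10 transformation, per-feature Welch tests and percent
    changes, QC-replicate coefficient-of-variation metrics, a from-scratch
    NIPALS PLS-DA implementation with Q2 cross-validation and
    leave-one-third-out classification validation, and accurate-mass plus
    MS/MS fragment-rule compound annotation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
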