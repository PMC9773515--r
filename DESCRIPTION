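Package: maveclass
Title: MAVE-Calibrated Clinical Variant Classification for Lynch Syndrome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns saturation-scale functional assay scores into clinical
    variant (re)classification for the Lynch syndrome gene MSH2. Provides
    functional tiering of missense variants from deep-mutational-scan
    loss-of-function scores and splice-disruption predictions, OddsPath
    calibration of functional evidence against curated control variants,
    a point-based ACMG/AMP evidence-code engine with PS3/BS3 assignment,
    exact two-sided Fisher and binomial tests, logistic cancer-association
    models, joint germline-somatic two-hit analyses of paired tumor-normal
    cohorts, and a synthetic cohort generator so every stage is testable
    without access to protected clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
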