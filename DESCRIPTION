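Package: gaitphase
Title: Interlimb Coordination and Load-Distribution Analysis for Quadrupedal Locomotion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quadrupedal interlimb coordination from
    pose-tracking and load-cell recordings: stride segmentation and
    cross-correlation interlimb phase estimation, circular statistics
    (von Mises kernel density estimation, mixture models, circular-linear
    regression with group effects), center-of-support biomechanics from
    vertical ground reaction forces, limb-support-pattern decomposition by
    principal components, and a permutation-tested classifier of phase
    lateralization. Includes a synthetic cohort generator with known ground
    truth so that every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    pracma,
    minpack.lm,
    lme4,
    lmerTest,
    e1071,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
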