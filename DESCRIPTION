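Package: gaitstress
Title: Gait and Psychosocial Stress Analysis from 2D Pose Keypoints
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pipeline for testing whether a measurement procedure induces
    psychosocial stress and alters treadmill gait. Extracts gait events,
    sagittal joint kinematics, stride-normalized waveforms and variability
    features from 2D pose-estimation keypoint trajectories; processes
    salivary cortisol series (baseline adjustment, responder classification)
    and PANAS/SSSQ questionnaires; and runs the group-comparison statistics:
    mixed and repeated-measures ANOVA with effect sizes, normality-gated
    pairwise tests with Bonferroni correction, and one-dimensional
    statistical parametric mapping with random-field-theory and permutation
    thresholds. A synthetic-data module generates keypoint, ground-reaction
    force, cortisol and questionnaire data with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
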