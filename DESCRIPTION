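Package: fixpupil
Title: Fixation-Aligned Pupillometry for Free-Viewing Visual Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tested pipeline for analysing pupil size recorded with a
    video-based eye tracker during free-viewing visual search. Covers blink
    reconstruction with derivative-based endpoint extension, downsampling and
    zero-phase Butterworth smoothing, regression-based correction of the pupil
    foreshortening error from an ellipse-tracking calibration task, fixation
    detection, selection and classification (discoveries, revisits, discovery
    order), baseline-normalised fixation-aligned epoch extraction and
    whole-trial averaging with bootstrap standard errors, and two-tailed
    cluster-corrected sign-flip permutation tests for one-dimensional pupil
    traces. A seeded synthetic-session generator with ground-truth bookkeeping
    exercises every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
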