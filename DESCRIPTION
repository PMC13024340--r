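Package: ivmetrics
Title: Automated Cervical Intervertebral Motion Instability Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Computes sagittal-plane intervertebral motion metrics for the
    subaxial cervical spine (C2-C7) from four corner landmarks per vertebra on
    paired flexion-extension radiographs: disc angles, intervertebral rotation,
    translation in percent endplate width and millimetres, anterior and
    posterior disc heights, and AMA-convention segment angles.  Fits normative
    reference models from asymptomatic cohorts (per-level statistics with 95%
    upper limits, rotation-dependent translation and disc-widening regressions
    with standard-error-of-forecast bands), scores motion segments with the
    standardized TI, AVI and PVI instability indices and standardized disc
    height, tabulates abnormality prevalence under rotation and effort filters,
    and selects diagnostic thresholds by ROC analysis with Youden's J.  A
    synthetic-data generator poses landmark exams with known kinematics so the
    full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
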