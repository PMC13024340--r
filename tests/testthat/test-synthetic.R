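test_that("zero-noise cohorts lie exactly on the configured lines", {
  cfg <- generatorConfig()
  cfg$levels$rdt_noise_sd[] <- 0
  cfg$rddw_anterior$noise_sd <- 0
  cfg$rddw_posterior$noise_sd <- 0
  d <- generateMetricCohort(cfg, n = 30, seed = 61)
  for (p in cervicalLevelPairs()) {
    i <- cfg$levels$level == p
    dd <- d[d$level == p, ]
    expect_equal(dd$translation_pct_epw,
                 cfg$levels$rdt_slope[i] * dd$rotation_deg +
                   cfg$levels$rdt_intercept[i], tolerance = 1e-12)
  }
  expect_equal(d$adh_ext - d$adh_flex,
               cfg$rddw_anterior$slope * d$rotation_deg, tolerance = 1e-12)
  expect_equal(d$pdh_flex - d$pdh_ext,
               cfg$rddw_posterior$slope * d$rotation_deg, tolerance = 1e-12)
  # refitting recovers the coefficients exactly
  m <- fitLinear(d$rotation_deg[d$level == "C4-C5"],
                 d$translation_pct_epw[d$level == "C4-C5"])
  i <- cfg$levels$level == "C4-C5"
  expect_equal(m$slope, cfg$levels$rdt_slope[i], tolerance = 1e-9)
  expect_equal(m$intercept, cfg$levels$rdt_intercept[i], tolerance = 1e-9)
  expect_equal(m$r_squared, 1, tolerance = 1e-9)
})

test_that("per-level rotation means concentrate on the configured targets", {
  cfg <- generatorConfig()
  n <- 300
  d <- generateMetricCohort(cfg, n = n, seed = 62)
  for (p in cervicalLevelPairs()) {
    i <- cfg$levels$level == p
    xbar <- mean(d$rotation_deg[d$level == p])
    expect_lt(abs(xbar - cfg$levels$rot_mean[i]),
              3 * cfg$levels$rot_sd[i] / sqrt(n))
  }
})

test_that("the effort multiplier scales global motion", {
  full <- generateMetricCohort(generatorConfig(effort = 1), n = 200,
                               seed = 63)
  low <- generateMetricCohort(generatorConfig(effort = 0.6), n = 200,
                              seed = 63)
  t_full <- mean(full$total_c2c7_rotation_deg[!duplicated(full$exam_id)])
  t_low <- mean(low$total_c2c7_rotation_deg[!duplicated(low$exam_id)])
  expect_equal(t_low / t_full, 0.6, tolerance = 0.05)
})

test_that("fixed seeds reproduce cohorts exactly", {
  cfg <- generatorConfig()
  a <- generateMetricCohort(cfg, n = 15, seed = 64)
  b <- generateMetricCohort(cfg, n = 15, seed = 64)
  expect_identical(a, b)
  e1 <- generateSectioningExperiment(cfg, n_per_arm = 4, seed = 65)
  e2 <- generateSectioningExperiment(cfg, n_per_arm = 4, seed = 65)
  expect_identical(e1, e2)
  l1 <- generateLandmarkCohort(cfg, n = 2, seed = 66)
  l2 <- generateLandmarkCohort(cfg, n = 2, seed = 66)
  expect_identical(l1$truth, l2$truth)
  expect_equal(l1$exams[[1]]$flexion$vertebrae$C4$corners,
               l2$exams[[1]]$flexion$vertebrae$C4$corners, tolerance = 0)
})

test_that("posing rejects infeasible prescriptions by segment name", {
  bad <- tibble::tibble(
    level = "C4-C5", rotation_deg = 15, translation_pct_epw = 15,
    adh_flex = -1, adh_ext = 20, pdh_flex = 20, pdh_ext = 12)
  expect_error(poseLandmarks(bad), "C4-C5")
  gap <- tibble::tibble(
    level = c("C2-C3", "C4-C5"),
    rotation_deg = 10, translation_pct_epw = 10,
    adh_flex = 15, adh_ext = 25, pdh_flex = 20, pdh_ext = 12)
  expect_error(poseLandmarks(gap), "contiguous")
})

test_that("a zero-motion exam measures zero everywhere", {
  truth <- tibble::tibble(
    level = cervicalLevelPairs(), rotation_deg = 0,
    translation_pct_epw = 0, adh_flex = 18, adh_ext = 18,
    pdh_flex = 18, pdh_ext = 18)
  ex <- poseLandmarks(truth, exam_id = "still", jitter = FALSE)
  m <- examMetrics(ex)
  expect_equal(m$rotation_deg, rep(0, 5), tolerance = 1e-9)
  expect_equal(m$translation_pct_epw, rep(0, 5), tolerance = 1e-9)
  expect_equal(m$total_c2c7_rotation_deg, rep(0, 5), tolerance = 1e-9)
})

test_that("global magnification of one phase leaves %EPW metrics unchanged", {
  cfg <- generatorConfig()
  truth <- generateMetricCohort(cfg, n = 1, seed = 67)
  ex <- poseLandmarks(truth, exam_id = "mag", jitter = FALSE)
  m0 <- examMetrics(ex)
  ex13 <- transformExam(ex, flex = list(angle = 0, scale = 1, shift = c(0, 0)),
                        ext = list(angle = 0, scale = 1.3, shift = c(0, 0)))
  m1 <- examMetrics(ex13)
  expect_equal(m1$translation_pct_epw, m0$translation_pct_epw,
               tolerance = 1e-9)
  expect_equal(m1$adh_flex, m0$adh_flex, tolerance = 1e-9)
  expect_equal(m1$rotation_deg, m0$rotation_deg, tolerance = 1e-9)
})

test_that("zero injury effects give chance-level discrimination", {
  cfg <- generatorConfig()
  cfg$injury$rotation_shift[] <- 0
  cfg$injury$dadh_shift[] <- 0
  cfg$injury$dpdh_shift[] <- 0
  ref <- fitReference(generateMetricCohort(cfg, n = 400, seed = 71))
  aucs <- vapply(1:10, function(s) {
    d <- generateSectioningExperiment(cfg, n_per_arm = 12, seed = 71 + s)
    sc <- scoreSegments(d, ref)
    tgt <- sc[sc$level == cfg$injury$target_level & !sc$excluded, ]
    rocCurve(tgt$avi, tgt$condition != "intact")$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.12)
})

test_that("default sectioning effects are detected by the vertical indices", {
  cfg <- generatorConfig()
  ref <- fitReference(generateMetricCohort(cfg, n = 400, seed = 72))
  d <- generateSectioningExperiment(cfg, n_per_arm = 12, seed = 73)
  sc <- scoreSegments(d, ref)
  tgt <- sc[sc$level == cfg$injury$target_level, ]
  rep <- sectioningReport(tgt, metrics = c("avi", "pvi",
                                           "translation_pct_epw"))
  auc <- stats::setNames(rep$auc, rep$metric)
  expect_gt(auc[["avi"]], 0.9)
  expect_gt(auc[["pvi"]], 0.9)
  expect_gt(auc[["avi"]], auc[["translation_pct_epw"]])
})

test_that("full-stack round trip: generate, pose, measure, score", {
  cfg <- generatorConfig()
  lc <- generateLandmarkCohort(cfg, n = 10, seed = 74)
  measured <- cohortMetrics(lc$exams)
  truth <- lc$truth
  key <- paste(truth$exam_id, truth$level)
  mkey <- paste(measured$exam_id, measured$level)
  ord <- match(key, mkey)
  expect_false(anyNA(ord))
  for (col in c("rotation_deg", "translation_pct_epw", "adh_flex",
                "adh_ext", "pdh_flex", "pdh_ext")) {
    expect_lt(max(abs(measured[[col]][ord] - truth[[col]])), 1e-6)
  }
  # flags from measured metrics match flags computed on the ground truth
  ref <- fitReference(generateMetricCohort(cfg, n = 300, seed = 75))
  s_meas <- scoreSegments(measured[ord, ], ref)
  s_true <- scoreSegments(truth, ref)
  expect_equal(s_meas$ti, s_true$ti, tolerance = 1e-5)
  expect_identical(s_meas$flag_avi, s_true$flag_avi)
  expect_identical(s_meas$excluded, s_true$excluded)
})
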