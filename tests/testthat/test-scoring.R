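# hand-built reference with known coefficients for arithmetic checks
toyReference <- function() {
  lm_of <- function(slope, intercept, n = 4, x_mean = 0, sxx = 10, s = 1) {
    structure(list(slope = slope, intercept = intercept, n = n,
                   x_mean = x_mean, sxx = sxx, residual_sd = s,
                   r_squared = 0.9), class = "ivm_linmod")
  }
  structure(list(
    version = "1.0",
    level_stats = tibble::tibble(),
    rdt = stats::setNames(
      replicate(5, lm_of(0.8, 2), simplify = FALSE), cervicalLevelPairs()),
    rddw_anterior = lm_of(0.8, 0),
    rddw_posterior = lm_of(0.6, 0),
    avg_dh_ref = tibble::tibble(metric = "avg_dh",
                                level = cervicalLevelPairs(),
                                n = 10, mean = 19, sd = 1.25,
                                upper95 = 19 + 1.96 * 1.25),
    c2c7 = list(mean = 74, sd = 14, n = 10),
    thresholds = defaultThresholds(),
    n_per_level = stats::setNames(rep(10L, 5), cervicalLevelPairs()),
    provenance = NULL
  ), class = "normative_reference")
}

segRow <- function(level = "C4-C5", rotation = 10, translation = 10,
                   adh_flex = 15, adh_ext = 25, pdh_flex = 22, pdh_ext = 14,
                   rot_diff = 3, angle_diff = 3, total = 70) {
  tibble::tibble(
    exam_id = "s", level = level, rotation_deg = rotation,
    translation_pct_epw = translation,
    translation_mm = translation / 100 * 14.9,
    adh_flex = adh_flex, adh_ext = adh_ext,
    pdh_flex = pdh_flex, pdh_ext = pdh_ext,
    avg_dh = mean(c(adh_flex, adh_ext, pdh_flex, pdh_ext)),
    rotation_diff_deg = rot_diff, segment_angle_diff_deg = angle_diff,
    total_c2c7_rotation_deg = total, rotation_pct_c2c7 = NA_real_)
}

test_that("TI index standardizes translation against the RDT forecast", {
  ref <- toyReference()
  # on the regression line -> 0
  expect_equal(tiIndex(0.8 * 10 + 2, 10, ref, "C4-C5"), 0)
  # closed-form check: SEF(2) = sqrt(1 + 1/4 + 4/10) with s = 1
  expect_equal(tiIndex(0.8 * 2 + 2 + 2 * sqrt(1.65), 2, ref, "C4-C5"), 2,
               tolerance = 1e-12)
  # hand arithmetic at the fitted mean: SEF(0) = sqrt(1.25)
  expect_equal(tiIndex(16, 0, ref, "C2-C3"), (16 - 2) / sqrt(1.25),
               tolerance = 1e-12)
  expect_error(tiIndex(10, 10, ref, "C9-C10"), "C9-C10")
})

test_that("AVI and PVI standardize the disc openings with correct sign", {
  ref <- toyReference()
  # anterior opening exactly as predicted -> 0
  expect_equal(aviIndex(25, 25 - 0.8 * 10, 10, ref), 0, tolerance = 1e-12)
  # opening = predicted + 3.2 SEF -> 3.2
  s10 <- sef(ref$rddw_anterior, 10)
  expect_equal(aviIndex(20 + 0.8 * 10 + 3.2 * s10, 20, 10, ref), 3.2,
               tolerance = 1e-12)
  # smaller-than-predicted opening -> negative
  expect_lt(aviIndex(20 + 0.8 * 10 - 1, 20, 10, ref), 0)
  # PVI uses pdh_flex - pdh_ext
  sp <- sef(ref$rddw_posterior, 10)
  expect_equal(pviIndex(14 + 0.6 * 10 + 2 * sp, 14, 10, ref), 2,
               tolerance = 1e-12)
})

test_that("classification applies exclusions and strict thresholds", {
  ref <- toyReference()
  # low-rotation segment is excluded and unflagged
  low <- classifySegment(segRow(rotation = 4.2), ref)
  expect_true(low$excluded)
  expect_match(low$exclusion_reason, "rotation < 5")
  expect_true(all(is.na(c(low$flag_ti, low$flag_avi, low$flag_trans))))
  # boundary translation of exactly 20 %EPW is normal (strict >)
  b <- classifySegment(segRow(translation = 20), ref)
  expect_false(b$flag_trans)
  expect_true(classifySegment(segRow(translation = 20.01), ref)$flag_trans)
  # retrolisthesis counts through the absolute value
  expect_true(classifySegment(segRow(translation = -21), ref)$flag_trans)
  # rotation difference 11.5 degrees is abnormal, 11 is not
  expect_true(classifySegment(segRow(rot_diff = 11.5), ref)$flag_rot_diff)
  expect_false(classifySegment(segRow(rot_diff = 11), ref)$flag_rot_diff)
  # mm criterion only when explicitly enabled
  expect_false("flag_trans_mm" %in% names(b))
  ref_mm <- ref
  ref_mm$thresholds$use_mm_criterion <- TRUE
  expect_true("flag_trans_mm" %in%
                names(classifySegment(segRow(), ref_mm)))
})

test_that("flags are monotone in the underlying values", {
  ref <- toyReference()
  base <- segRow(translation = 19)
  for (tr in c(20.5, 25, 40)) {
    prev <- classifySegment(base, ref)$flag_trans
    cur <- classifySegment(segRow(translation = tr), ref)$flag_trans
    expect_true(cur >= prev)
    base <- segRow(translation = tr)
  }
})

test_that("effort filter keeps only adequately stressed exams", {
  m <- rbind(segRow(total = 59), segRow(total = 61), segRow(total = NA))
  m$exam_id <- c("a", "b", "c")
  kept <- effortFilter(m, 60)
  expect_identical(kept$exam_id, "b")
  expect_identical(effortFilter(m, NULL), m)
  expect_warning(e <- effortFilter(m[3, ], 60), "removed every exam")
  expect_equal(nrow(e), 0)
  # selection property: filtering never lowers the mean total rotation
  cfg <- generatorConfig()
  d <- generateMetricCohort(cfg, n = 80, seed = 41)
  f <- effortFilter(d, 60)
  expect_gte(mean(f$total_c2c7_rotation_deg), mean(d$total_c2c7_rotation_deg))
})

test_that("prevalence percentages match brute-force counting", {
  ref <- toyReference()
  cfg <- generatorConfig()
  d <- generateMetricCohort(cfg, n = 10, seed = 42)  # 50 segments
  sc <- scoreSegments(d, ref)
  tab <- prevalence(sc)
  for (p in cervicalLevelPairs()) {
    dd <- sc[sc$level == p & !sc$excluded, ]
    expect_equal(tab$n[tab$level == p], nrow(dd))
    f <- dd$flag_ti[!is.na(dd$flag_ti)]
    expect_equal(tab$pct_ti[tab$level == p],
                 if (length(f)) 100 * sum(f) / length(f) else NA_real_)
    g <- dd$flag_rot_diff[!is.na(dd$flag_rot_diff)]
    expect_equal(tab$pct_rot_diff[tab$level == p],
                 if (length(g)) 100 * sum(g) / length(g) else NA_real_)
  }
  # ten segments with one flagged -> 10%
  one <- scoreSegments(
    do.call(rbind, c(replicate(9, segRow(translation = 5),
                               simplify = FALSE),
                     list(segRow(translation = 30)))), ref)
  expect_equal(prevalence(one)$pct_trans[3], 10)
})

test_that("prevalence is invariant to ordering and cohort duplication", {
  ref <- toyReference()
  cfg <- generatorConfig()
  d <- generateMetricCohort(cfg, n = 12, seed = 43)
  sc <- scoreSegments(d, ref)
  t1 <- prevalence(sc)
  t2 <- prevalence(sc[sample.int(nrow(sc)), ])
  t3 <- prevalence(rbind(sc, sc))
  expect_equal(t2[, -2], t1[, -2])
  expect_equal(t3[, -2], t1[, -2])
  expect_equal(t3$n, 2 * t1$n)
})

test_that("an all-excluded level yields an empty prevalence row", {
  ref <- toyReference()
  sc <- scoreSegments(rbind(segRow(rotation = 1), segRow(rotation = 2)), ref)
  tab <- prevalence(sc)
  expect_equal(tab$n[tab$level == "C4-C5"], 0)
  expect_true(is.na(tab$pct_ti[tab$level == "C4-C5"]))
})
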