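#' Maximum absolute difference of a per-level value vs adjacent levels
#'
#' Reference tables and the AMA alteration-of-motion-segment-integrity
#' criteria compare a level against its immediate neighbors: the statistic is
#' the maximum absolute difference between the value at the query level pair
#' and the value at each available adjacent level pair.  C2-C3 and C6-C7
#' have a single neighbor.
#'
#' @param values Named numeric vector keyed by level pair (missing or `NA`
#'   entries are unavailable levels).
#' @param pair Query level pair.
#' @return The maximum absolute difference, or `NA` when no neighbor value
#'   is available (undefined, not zero).
#' @export
adjacentLevelDifference <- function(values, pair) {
  if (!pair %in% names(values) || is.na(values[[pair]])) return(NA_real_)
  nb <- adjacentPairs(pair)
  nbv <- values[intersect(nb, names(values))]
  nbv <- nbv[!is.na(nbv)]
  if (length(nbv) == 0L) return(NA_real_)
  max(abs(values[[pair]] - nbv))
}

#' Compute all per-segment motion metrics for one exam
#'
#' For every motion segment whose two vertebrae are present in both phases:
#' disc angles, intervertebral rotation (extension minus flexion),
#' translation in percent endplate width and in millimetres, anterior and
#' posterior disc heights per phase, their mean (`avg_dh`), AMA-convention
#' segment angles, and the adjacent-level difference statistics (rotation
#' differences from the flexion-extension rotations; segment-angle
#' differences from the flexion radiograph only).  When both C2 and C7 are
#' analyzable in both phases the total C2-C7 rotation (relative rotation of
#' C2 with respect to C7, which equals the sum of the segmental rotations
#' for rigid vertebrae) and each segment's share of it are added.
#'
#' @param exam An [examLandmarks()] object.
#' @param epw_mm Named per-level endplate widths in mm used to convert
#'   translation to millimetres; defaults to [defaultEndplateWidthsMm()].
#' @return A tibble with one row per available segment and columns
#'   `exam_id, level, rotation_deg, translation_pct_epw, translation_mm,
#'   adh_flex, adh_ext, pdh_flex, pdh_ext, avg_dh, disc_angle_flex,
#'   disc_angle_ext, segment_angle_flex, segment_angle_ext,
#'   rotation_diff_deg, segment_angle_diff_deg, total_c2c7_rotation_deg,
#'   rotation_pct_c2c7, degeneration, condition`.  Unavailable quantities
#'   are `NA`.
#' @export
examMetrics <- function(exam, epw_mm = defaultEndplateWidthsMm()) {
  stopifnot(inherits(exam, "exam_landmarks"))
  facing <- exam$flexion$facing
  segs <- availableSegments(exam)
  rows <- lapply(segs, function(pair) {
    sup_l <- sub("-.*", "", pair)
    inf_l <- sub(".*-", "", pair)
    sf <- exam$flexion$vertebrae[[sup_l]]
    se <- exam$extension$vertebrae[[sup_l]]
    jf <- exam$flexion$vertebrae[[inf_l]]
    je <- exam$extension$vertebrae[[inf_l]]
    da_f <- discAngle(sf, jf, facing)
    da_e <- discAngle(se, je, facing)
    dh_f <- discHeights(sf, jf, facing)
    dh_e <- discHeights(se, je, facing)
    trans <- intervertebralTranslation(sf, se, jf, je, facing)
    w_mm <- if (pair %in% names(epw_mm)) epw_mm[[pair]] else NA_real_
    tibble::tibble(
      exam_id = exam$exam_id,
      level = pair,
      rotation_deg = intervertebralRotation(da_f, da_e),
      translation_pct_epw = trans,
      translation_mm = trans / 100 * w_mm,
      adh_flex = dh_f[["dh_A"]], adh_ext = dh_e[["dh_A"]],
      pdh_flex = dh_f[["dh_P"]], pdh_ext = dh_e[["dh_P"]],
      avg_dh = mean(c(dh_f, dh_e)),
      disc_angle_flex = da_f, disc_angle_ext = da_e,
      segment_angle_flex = segmentAngle(sf, jf, facing),
      segment_angle_ext = segmentAngle(se, je, facing)
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- examMetricsEmpty(exam$exam_id)
  } else {
    rot <- stats::setNames(out$rotation_deg, out$level)
    sa <- stats::setNames(out$segment_angle_flex, out$level)
    out$rotation_diff_deg <- vapply(out$level, function(p)
      adjacentLevelDifference(rot, p), numeric(1))
    out$segment_angle_diff_deg <- vapply(out$level, function(p)
      adjacentLevelDifference(sa, p), numeric(1))
    total <- NA_real_
    both <- intersect(names(exam$flexion$vertebrae),
                      names(exam$extension$vertebrae))
    if (all(c("C2", "C7") %in% both)) {
      total <- vertebraRotationChange(exam$flexion$vertebrae[["C2"]],
                                      exam$extension$vertebrae[["C2"]],
                                      facing) -
        vertebraRotationChange(exam$flexion$vertebrae[["C7"]],
                               exam$extension$vertebrae[["C7"]], facing)
    }
    out$total_c2c7_rotation_deg <- total
    out$rotation_pct_c2c7 <- if (is.na(total)) NA_real_ else
      100 * out$rotation_deg / total
  }
  out$degeneration <- if (is.null(exam$degeneration)) NA_real_ else
    as.numeric(exam$degeneration[out$level])
  out$condition <- if (is.null(exam$condition)) NA_character_ else
    exam$condition
  out
}

examMetricsEmpty <- function(exam_id) {
  tibble::tibble(
    exam_id = character(0), level = character(0),
    rotation_deg = numeric(0), translation_pct_epw = numeric(0),
    translation_mm = numeric(0),
    adh_flex = numeric(0), adh_ext = numeric(0),
    pdh_flex = numeric(0), pdh_ext = numeric(0), avg_dh = numeric(0),
    disc_angle_flex = numeric(0), disc_angle_ext = numeric(0),
    segment_angle_flex = numeric(0), segment_angle_ext = numeric(0),
    rotation_diff_deg = numeric(0), segment_angle_diff_deg = numeric(0),
    total_c2c7_rotation_deg = numeric(0), rotation_pct_c2c7 = numeric(0)
  )
}

#' Compute metrics for a collection of exams
#'
#' @param exams List of [examLandmarks()] objects.
#' @inheritParams examMetrics
#' @return One tibble, rows from all exams stacked (see [examMetrics()]).
#' @export
cohortMetrics <- function(exams, epw_mm = defaultEndplateWidthsMm()) {
  do.call(rbind, lapply(exams, examMetrics, epw_mm = epw_mm))
}
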