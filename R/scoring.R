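#' Translational instability index
#'
#' Observed translation minus the translation predicted from rotation by the
#' level's rotation-dependent translation regression, in units of the
#' standard error of the forecast at that rotation:
#' `TI = (translation - (M_RDT * rotation + B_RDT)) / SEF_RDT(rotation)`.
#' Values in \[-2, 2\] are within normal limits.
#'
#' @param translation_pct_epw Observed translation (percent endplate width).
#' @param rotation_deg Observed intervertebral rotation (degrees).
#' @param ref A [fitReference()] model.
#' @param level Level pair (selects the per-level RDT model).
#' @return Dimensionless index (vectorized over the first two arguments).
#' @export
tiIndex <- function(translation_pct_epw, rotation_deg, ref, level) {
  m <- ref$rdt[[level]]
  if (is.null(m)) stop("no RDT model for level ", level)
  standardizeToForecast(translation_pct_epw, rotation_deg, m)
}

#' Anterior vertical instability index
#'
#' Standardizes the anterior disc opening `adh_ext - adh_flex` against the
#' pooled anterior rotation-dependent disc-widening regression:
#' `AVI = ((ADH_ext - ADH_flex) - (M_RDDW * rotation + B_RDDW)) / SEF_RDDW(rotation)`.
#'
#' @param adh_ext,adh_flex Anterior disc heights in extension and flexion
#'   (percent endplate width).
#' @inheritParams tiIndex
#' @return Dimensionless index.
#' @export
aviIndex <- function(adh_ext, adh_flex, rotation_deg, ref) {
  standardizeToForecast(adh_ext - adh_flex, rotation_deg, ref$rddw_anterior)
}

#' Posterior vertical instability index
#'
#' As [aviIndex()] with the posterior opening `pdh_flex - pdh_ext` and the
#' pooled posterior disc-widening regression.
#'
#' @param pdh_flex,pdh_ext Posterior disc heights in flexion and extension
#'   (percent endplate width).
#' @inheritParams tiIndex
#' @return Dimensionless index.
#' @export
pviIndex <- function(pdh_flex, pdh_ext, rotation_deg, ref) {
  standardizeToForecast(pdh_flex - pdh_ext, rotation_deg, ref$rddw_posterior)
}

standardizeToForecast <- function(observed, rotation, model) {
  s <- sef(model, rotation)
  if (any(s <= 0, na.rm = TRUE)) {
    stop("degenerate reference: standard error of the forecast is zero")
  }
  (observed - predictLinear(model, rotation)) / s
}

#' Score every segment of a metric table against a reference
#'
#' Computes the TI, AVI, PVI and SDH indices and all abnormality flags for
#' each segment row.  Segments rotating less than the reference's
#' `min_rotation` (or missing rotation) are marked excluded, carry no flags,
#' and report the exclusion reason.  All criteria are strict inequalities --
#' boundary values are normal:
#' `TI > 2`, `AVI > 2`, `PVI > 2`, `SDH < -2`, rotation difference `> 11`
#' degrees, flexion segment-angle difference `> 11` degrees,
#' `|translation| > 20` percent endplate width (sign-agnostic so both
#' anterolisthesis and retrolisthesis count).  The legacy `> 3.5 mm`
#' translation flag is only computed when
#' `ref$thresholds$use_mm_criterion` is `TRUE`.
#'
#' @param metrics Segment-level tibble ([cohortMetrics()] or the synthetic
#'   generator's output).
#' @param ref A [fitReference()] model.
#' @return The input tibble with appended columns `ti, avi, pvi, sdh`,
#'   logical flags `flag_ti, flag_avi, flag_pvi, flag_sdh, flag_rot_diff,
#'   flag_angle_diff, flag_trans` (and `flag_trans_mm` when enabled),
#'   `excluded` and `exclusion_reason`.
#' @export
scoreSegments <- function(metrics, ref) {
  stopifnot(inherits(ref, "normative_reference"))
  th <- ref$thresholds
  n <- nrow(metrics)
  out <- metrics
  out$ti <- out$avi <- out$pvi <- out$sdh <- NA_real_
  excl_reason <- rep(NA_character_, n)
  rot <- metrics$rotation_deg
  excluded <- is.na(rot) | rot < th$min_rotation
  excl_reason[is.na(rot)] <- "missing rotation"
  excl_reason[!is.na(rot) & rot < th$min_rotation] <-
    sprintf("rotation < %g deg", th$min_rotation)

  dh_ref <- ref$avg_dh_ref
  for (p in cervicalLevelPairs()) {
    i <- which(metrics$level == p & !excluded)
    if (!length(i)) next
    out$ti[i] <- tiIndex(metrics$translation_pct_epw[i], rot[i], ref, p)
    out$avi[i] <- aviIndex(metrics$adh_ext[i], metrics$adh_flex[i], rot[i],
                           ref)
    out$pvi[i] <- pviIndex(metrics$pdh_flex[i], metrics$pdh_ext[i], rot[i],
                           ref)
    r <- dh_ref[dh_ref$level == p, ]
    if (nrow(r) == 1L && r$sd > 0) {
      out$sdh[i] <- standardizedDiscHeight(metrics$avg_dh[i], r$mean, r$sd)
    }
  }

  lim <- th$index_limit
  flagOf <- function(value, cond) ifelse(excluded, NA, cond & !is.na(value))
  out$flag_ti <- flagOf(out$ti, out$ti > lim)
  out$flag_avi <- flagOf(out$avi, out$avi > lim)
  out$flag_pvi <- flagOf(out$pvi, out$pvi > lim)
  out$flag_sdh <- flagOf(out$sdh, out$sdh < -lim)
  out$flag_rot_diff <- flagOf(metrics$rotation_diff_deg,
                              metrics$rotation_diff_deg > th$rotation_diff_limit)
  out$flag_angle_diff <- flagOf(metrics$segment_angle_diff_deg,
                                metrics$segment_angle_diff_deg > th$angle_diff_limit)
  out$flag_trans <- flagOf(metrics$translation_pct_epw,
                           abs(metrics$translation_pct_epw) > th$translation_limit)
  if (isTRUE(th$use_mm_criterion)) {
    out$flag_trans_mm <- flagOf(metrics$translation_mm,
                                abs(metrics$translation_mm) > th$translation_mm_limit)
  }
  out$excluded <- excluded
  out$exclusion_reason <- excl_reason
  out
}

#' Score a single segment
#'
#' Convenience wrapper over [scoreSegments()] for one metric row.
#'
#' @param segment One-row segment tibble (or a row of a metric table).
#' @param ref A [fitReference()] model.
#' @return One-row scored tibble.
#' @export
classifySegment <- function(segment, ref) {
  scoreSegments(segment[1, , drop = FALSE], ref)
}

#' Exam-level effort filter on total C2-C7 rotation
#'
#' Keeps only segments belonging to exams whose total C2-C7 rotation
#' strictly exceeds `min_total` degrees; when the filter is active, exams
#' whose total is unavailable (C2 or C7 not analyzable in both phases) are
#' dropped.  `min_total = NULL` disables the filter (identity).
#'
#' @param metrics Segment-level tibble with a `total_c2c7_rotation_deg`
#'   column.
#' @param min_total Minimum total rotation in degrees (default 60).
#' @return Filtered tibble.
#' @export
effortFilter <- function(metrics, min_total = 60) {
  if (is.null(min_total)) return(metrics)
  stopifnot(min_total >= 0)
  tot <- metrics$total_c2c7_rotation_deg
  keep <- !is.na(tot) & tot > min_total
  if (!any(keep)) {
    warning("effort filter removed every exam (no totals > ", min_total,
            " deg)")
  }
  metrics[keep, , drop = FALSE]
}

prevalenceCriteria <- function() {
  c(ti = "flag_ti", avi = "flag_avi", pvi = "flag_pvi", sdh = "flag_sdh",
    rot_diff = "flag_rot_diff", angle_diff = "flag_angle_diff",
    trans = "flag_trans")
}

#' Tabulate abnormality prevalence per level
#'
#' For each level pair and abnormality criterion, the percentage of flagged
#' segments among analyzable segments.  Denominators count non-excluded
#' segments whose inputs for that criterion are available, so criteria with
#' missing inputs (e.g. a level with no neighbor for the difference
#' statistics) do not deflate the estimate; `n` is the number of
#' non-excluded segments at the level.
#'
#' @param scored Output of [scoreSegments()].
#' @param criteria Character vector naming flag columns to tabulate;
#'   defaults to the seven standard criteria.
#' @return Tibble with one row per level: `level, n`, then one percentage
#'   column per criterion (named `pct_<criterion>`).
#' @export
prevalence <- function(scored, criteria = prevalenceCriteria()) {
  stopifnot(all(criteria %in% names(scored)))
  rows <- lapply(cervicalLevelPairs(), function(p) {
    d <- scored[scored$level == p & !scored$excluded, , drop = FALSE]
    row <- tibble::tibble(level = p, n = nrow(d))
    for (k in seq_along(criteria)) {
      f <- d[[criteria[k]]]
      nm <- if (!is.null(names(criteria)) && nzchar(names(criteria)[k]))
        names(criteria)[k] else criteria[k]
      row[[paste0("pct_", nm)]] <-
        if (sum(!is.na(f)) == 0L) NA_real_ else 100 * mean(f, na.rm = TRUE)
    }
    row
  })
  do.call(rbind, rows)
}
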