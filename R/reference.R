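#' Filter segment records for normative reference fitting
#'
#' Reference data come from radiographically normal, adequately stressed
#' segments: levels with intervertebral rotation below `min_rotation`
#' degrees are excluded (too little motion to engage the intrinsic
#' restraints; the cut keeps rotation equal to the threshold), and if
#' degeneration grades are available, levels at or above the definite
#' degeneration cutoff are excluded.
#'
#' @param metrics Segment-level tibble as produced by [cohortMetrics()] or
#'   [generateMetricCohort()]; an optional `degeneration` column holds
#'   Kellgren-Lawrence ordinal grades.
#' @param min_rotation Minimum rotation in degrees (default 5; segments with
#'   rotation < `min_rotation` are dropped).
#' @param degeneration_cutoff Grades `>= degeneration_cutoff` count as
#'   definite degeneration (default 2); ungraded (`NA`) segments are kept.
#' @return The filtered tibble.
#' @export
filterReferenceLevels <- function(metrics, min_rotation = 5,
                                  degeneration_cutoff = 2) {
  stopifnot(min_rotation >= 0)
  keep <- !is.na(metrics$rotation_deg) & metrics$rotation_deg >= min_rotation
  if ("degeneration" %in% names(metrics)) {
    g <- metrics$degeneration
    keep <- keep & (is.na(g) | g < degeneration_cutoff)
  }
  metrics[keep, , drop = FALSE]
}

#' Per-level reference statistics for one metric
#'
#' Sample mean, sample standard deviation (n - 1 denominator) and the upper
#' 95% reference limit `mean + 1.96 sd` for one metric column, per level
#' pair.  Levels with fewer than two records are omitted with a warning.
#'
#' @param metrics Segment-level tibble.
#' @param metric Name of the numeric column to summarize.
#' @return Tibble with columns `metric, level, n, mean, sd, upper95`.
#' @export
fitLevelStats <- function(metrics, metric) {
  stopifnot(metric %in% names(metrics))
  out <- lapply(cervicalLevelPairs(), function(p) {
    x <- metrics[[metric]][metrics$level == p]
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(NULL)  # level absent from the cohort
    if (length(x) < 2L) {
      warning("level ", p, ": fewer than 2 records for ", metric,
              "; omitted")
      return(NULL)
    }
    tibble::tibble(metric = metric, level = p, n = length(x),
                   mean = mean(x), sd = stats::sd(x),
                   upper95 = upperLimit95(mean(x), stats::sd(x)))
  })
  do.call(rbind, out)
}

#' Simple linear regression with forecast-error bookkeeping
#'
#' Ordinary least squares of `y` on `x`, retaining everything the standard
#' error of the forecast needs: slope, intercept, n, mean of x, centered sum
#' of squares of x, residual standard deviation (n - 2 denominator) and
#' R-squared.
#'
#' @param x,y Numeric vectors (pairs with `NA` in either are dropped).
#' @return Object of class `ivm_linmod`.
#' @export
fitLinear <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("linear fit requires at least 3 complete observations")
  if (stats::sd(x) <= .Machine$double.eps^0.5 * max(1, abs(mean(x)))) {
    stop("linear fit requires non-constant x")
  }
  fit <- stats::lm(y ~ x)
  # summary.lm warns on an exact fit; residual_sd 0 is a valid outcome here
  sm <- suppressWarnings(summary(fit))
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    n = n,
    x_mean = mean(x),
    sxx = sum((x - mean(x))^2),
    residual_sd = sm$sigma,
    r_squared = sm$r.squared
  ), class = "ivm_linmod")
}

#' @export
print.ivm_linmod <- function(x, ...) {
  cat(sprintf(
    "<ivm_linmod> y = %.4f x + %.4f  (n = %d, s = %.4f, R^2 = %.3f)\n",
    x$slope, x$intercept, x$n, x$residual_sd, x$r_squared))
  invisible(x)
}

#' Predicted value from a fitted linear model
#'
#' @param model An `ivm_linmod` from [fitLinear()].
#' @param x0 Predictor value(s).
#' @return Numeric prediction(s).
#' @export
predictLinear <- function(model, x0) {
  model$slope * x0 + model$intercept
}

#' Standard error of the forecast
#'
#' Point-specific prediction uncertainty of a simple linear regression at a
#' new predictor value:
#' `SEF(x0) = s * sqrt(1 + 1/n + (x0 - x_mean)^2 / sxx)`.
#' It exceeds the residual standard deviation everywhere and is minimal at
#' the mean of the fitted x.
#'
#' @param model An `ivm_linmod` from [fitLinear()].
#' @param x0 Predictor value(s) at which to evaluate (vectorized).
#' @return SEF in the units of the fitted response.
#' @export
sef <- function(model, x0) {
  model$residual_sd *
    sqrt(1 + 1 / model$n + (x0 - model$x_mean)^2 / model$sxx)
}

#' Standardized disc height
#'
#' Number of reference standard deviations by which a segment's average disc
#' height differs from the asymptomatic reference mean:
#' `SDH = (avg_dh - ref_mean) / ref_sd`.  Negative values indicate a disc
#' narrower than reference.
#'
#' @param avg_dh Subject average disc height (percent endplate width).
#' @param ref_mean,ref_sd Reference mean and standard deviation for the
#'   level (`ref_sd` must be positive).
#' @return Dimensionless z-score.
#' @export
standardizedDiscHeight <- function(avg_dh, ref_mean, ref_sd) {
  if (any(ref_sd <= 0)) stop("reference standard deviation must be positive")
  (avg_dh - ref_mean) / ref_sd
}

#' Fit the full normative reference model
#'
#' From a segment-level table of an asymptomatic cohort (after applying
#' [filterReferenceLevels()] internally), fits everything the scoring module
#' consumes:
#' \itemize{
#'   \item per-level statistics (mean, sd, 95% upper limit) for rotation,
#'     translation (%EPW and mm), rotation difference, segment-angle
#'     difference and rotation share of total C2-C7 motion;
#'   \item per-level rotation-dependent translation (RDT) regressions;
#'   \item pooled rotation-dependent disc-widening (RDDW) regressions for
#'     the anterior opening `adh_ext - adh_flex` and the posterior opening
#'     `pdh_flex - pdh_ext` (slopes are near-identical across levels, so a
#'     single relation per side is fitted on all levels combined);
#'   \item per-level average disc height reference (mean, sd) for SDH;
#'   \item total C2-C7 rotation statistics (one value per exam);
#'   \item the abnormality thresholds ([defaultThresholds()]).
#' }
#'
#' @param metrics Segment-level tibble ([cohortMetrics()] /
#'   [generateMetricCohort()]); optional `degeneration` column used for
#'   exclusion.
#' @param min_rotation,degeneration_cutoff Passed to
#'   [filterReferenceLevels()].
#' @param thresholds Threshold list, defaults to [defaultThresholds()]
#'   (with `min_rotation` recorded in it).
#' @param provenance Optional free-form list stored with the model (e.g.
#'   generator seed for synthetic references).
#' @return Object of class `normative_reference`.
#' @export
fitReference <- function(metrics, min_rotation = 5, degeneration_cutoff = 2,
                         thresholds = defaultThresholds(),
                         provenance = NULL) {
  thresholds$min_rotation <- min_rotation
  rec <- filterReferenceLevels(metrics, min_rotation, degeneration_cutoff)
  if (nrow(rec) == 0L) stop("no segments remain after reference filtering")

  stat_metrics <- c("rotation_deg", "translation_pct_epw", "translation_mm",
                    "rotation_diff_deg", "segment_angle_diff_deg",
                    "rotation_pct_c2c7")
  stat_metrics <- intersect(stat_metrics, names(rec))
  level_stats <- do.call(rbind, lapply(stat_metrics, function(m)
    fitLevelStats(rec, m)))

  rdt <- lapply(stats::setNames(nm = cervicalLevelPairs()), function(p) {
    d <- rec[rec$level == p, ]
    if (nrow(d) < 3L) {
      stop("level ", p, ": too few reference segments (", nrow(d),
           ") to fit the rotation-dependent translation regression")
    }
    fitLinear(d$rotation_deg, d$translation_pct_epw)
  })

  rddw_a <- fitLinear(rec$rotation_deg, rec$adh_ext - rec$adh_flex)
  rddw_p <- fitLinear(rec$rotation_deg, rec$pdh_flex - rec$pdh_ext)

  avg_dh_ref <- fitLevelStats(rec, "avg_dh")

  c2c7 <- list(mean = NA_real_, sd = NA_real_, n = 0L)
  if ("total_c2c7_rotation_deg" %in% names(rec)) {
    tot <- rec$total_c2c7_rotation_deg[!duplicated(rec$exam_id)]
    tot <- tot[!is.na(tot)]
    if (length(tot) >= 2L) {
      c2c7 <- list(mean = mean(tot), sd = stats::sd(tot), n = length(tot))
    }
  }

  structure(list(
    version = "1.0",
    level_stats = level_stats,
    rdt = rdt,
    rddw_anterior = rddw_a,
    rddw_posterior = rddw_p,
    avg_dh_ref = avg_dh_ref,
    c2c7 = c2c7,
    thresholds = thresholds,
    n_per_level = stats::setNames(
      vapply(cervicalLevelPairs(), function(p) sum(rec$level == p),
             integer(1)),
      cervicalLevelPairs()),
    provenance = provenance
  ), class = "normative_reference")
}

#' @export
print.normative_reference <- function(x, ...) {
  cat("<normative_reference> version ", x$version, "\n", sep = "")
  cat("  segments per level: ",
      paste(names(x$n_per_level), x$n_per_level, sep = "=", collapse = " "),
      "\n", sep = "")
  cat(sprintf("  total C2-C7 rotation: %.1f +/- %.1f deg (n = %d)\n",
              x$c2c7$mean, x$c2c7$sd, x$c2c7$n))
  cat(sprintf("  RDDW anterior R^2 = %.2f, posterior R^2 = %.2f\n",
              x$rddw_anterior$r_squared, x$rddw_posterior$r_squared))
  invisible(x)
}

linmodToList <- function(m) {
  m[c("slope", "intercept", "n", "x_mean", "sxx", "residual_sd", "r_squared")]
}

linmodFromList <- function(l) {
  need <- c("slope", "intercept", "n", "x_mean", "sxx", "residual_sd",
            "r_squared")
  if (!all(need %in% names(l))) stop("malformed linear-model record")
  structure(l[need], class = "ivm_linmod")
}

#' Serialize / restore a normative reference model
#'
#' JSON round trip carrying version, per-level sample sizes and provenance;
#' [loadReference()] validates that every level pair has an RDT model.
#'
#' @param ref A `normative_reference`.
#' @param path File path.
#' @return `saveReference()` returns `path` invisibly; `loadReference()`
#'   the restored `normative_reference`.
#' @export
saveReference <- function(ref, path) {
  stopifnot(inherits(ref, "normative_reference"))
  obj <- list(
    version = ref$version,
    level_stats = ref$level_stats,
    rdt = lapply(ref$rdt, linmodToList),
    rddw_anterior = linmodToList(ref$rddw_anterior),
    rddw_posterior = linmodToList(ref$rddw_posterior),
    avg_dh_ref = ref$avg_dh_ref,
    c2c7 = ref$c2c7,
    thresholds = ref$thresholds,
    n_per_level = as.list(ref$n_per_level),
    provenance = ref$provenance
  )
  writeLines(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE,
                              null = "null", pretty = TRUE), path)
  invisible(path)
}

#' @rdname saveReference
#' @export
loadReference <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  missing_rdt <- setdiff(cervicalLevelPairs(), names(x$rdt))
  if (length(missing_rdt)) {
    stop("reference file ", path, ": missing RDT model for ",
         paste(missing_rdt, collapse = ", "))
  }
  structure(list(
    version = x$version,
    level_stats = tibble::as_tibble(x$level_stats),
    rdt = lapply(x$rdt, linmodFromList),
    rddw_anterior = linmodFromList(x$rddw_anterior),
    rddw_posterior = linmodFromList(x$rddw_posterior),
    avg_dh_ref = tibble::as_tibble(x$avg_dh_ref),
    c2c7 = x$c2c7,
    thresholds = x$thresholds,
    n_per_level = unlist(x$n_per_level),
    provenance = x$provenance
  ), class = "normative_reference")
}
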