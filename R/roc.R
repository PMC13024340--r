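#' ROC curve with Youden-optimal threshold
#'
#' Builds the full ROC curve of a numeric metric against binary labels.
#' Candidate cutoffs are the midpoints between consecutive distinct sorted
#' values plus infinite sentinels; classification is strict (`value >
#' threshold` is called positive when `direction = "greater"`, `value <
#' threshold` when `"less"`).  The area under the curve is the trapezoidal
#' integral over the false-positive rate, which equals the pairwise
#' concordance (Mann-Whitney) statistic with ties counted one half.
#' Youden's J (`sensitivity + specificity - 1`) is maximized over all
#' candidate cutoffs; at ties the most sensitive cutoff is returned.
#'
#' @param values Numeric metric values.
#' @param labels Logical (or 0/1) vector; `TRUE` is the positive class
#'   (e.g. sectioned, vs intact negative).
#' @param direction `"greater"` if larger values indicate the positive
#'   class, `"less"` otherwise.
#' @return Object of class `ivm_roc`: list with `points` (tibble
#'   `threshold, fpr, tpr` ordered along the curve), `auc`, `youden`
#'   (list `threshold, sensitivity, specificity, j`) and `direction`.
#' @export
rocCurve <- function(values, labels, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  ok <- is.finite(values) & !is.na(labels)
  values <- values[ok]; labels <- labels[ok]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC requires at least one positive and one negative label")
  }
  v <- if (direction == "greater") values else -values
  sv <- sort(unique(v))
  thr <- c(-Inf, if (length(sv) > 1L) (sv[-1] + sv[-length(sv)]) / 2, Inf)
  tpr <- vapply(thr, function(t) sum(v > t & labels) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(v > t & !labels) / n_neg, numeric(1))
  thr_out <- if (direction == "greater") thr else -thr
  ord <- order(fpr, tpr)
  points <- tibble::tibble(threshold = thr_out[ord], fpr = fpr[ord],
                           tpr = tpr[ord])
  auc <- sum(diff(points$fpr) * (points$tpr[-1] + points$tpr[-nrow(points)]) / 2)

  j <- tpr - fpr
  best <- which(j >= max(j) - 1e-12)
  # most sensitive maximizer; in transformed units that is the smallest
  # threshold (sensitivity is non-increasing in the transformed threshold)
  pick <- best[which.min(thr[best])]
  youden <- list(threshold = thr_out[pick],
                 sensitivity = tpr[pick],
                 specificity = 1 - fpr[pick],
                 j = j[pick])
  structure(list(points = points, auc = auc, youden = youden,
                 direction = direction, n_pos = n_pos, n_neg = n_neg),
            class = "ivm_roc")
}

#' @export
print.ivm_roc <- function(x, ...) {
  cat(sprintf(
    "<ivm_roc> AUC = %.3f (%d pos / %d neg); Youden J = %.3f at %s %.4g (sens %.2f, spec %.2f)\n",
    x$auc, x$n_pos, x$n_neg, x$youden$j,
    if (x$direction == "greater") ">" else "<",
    x$youden$threshold, x$youden$sensitivity, x$youden$specificity))
  invisible(x)
}

#' Area under an ROC curve
#'
#' @param roc An `ivm_roc` from [rocCurve()].
#' @return AUC in \[0, 1\].
#' @export
rocAuc <- function(roc) {
  stopifnot(inherits(roc, "ivm_roc"))
  roc$auc
}

#' Youden-optimal operating point of an ROC curve
#'
#' @param roc An `ivm_roc` from [rocCurve()].
#' @return List `threshold, sensitivity, specificity, j`.
#' @export
youdenOptimal <- function(roc) {
  stopifnot(inherits(roc, "ivm_roc"))
  roc$youden
}

#' Diagnostic-performance table for candidate instability metrics
#'
#' For a scored cohort with condition labels (e.g. a cadaveric sequential
#' ligament-sectioning experiment), computes per metric the AUC, the
#' Youden-optimal threshold and the sensitivity and specificity at that
#' threshold.  Labels other than `intact_label` form the positive class;
#' stages can be pooled (default) or analyzed one stage vs intact.
#'
#' @param scored Tibble with a `condition` column and metric columns.
#' @param metrics Character vector of metric column names; metrics absent
#'   from `scored` are skipped with a warning.
#' @param intact_label Negative-class condition label (default
#'   `"intact"`).
#' @param stage Optional single stage label: restrict positives to that
#'   stage instead of pooling all sectioned stages.
#' @param directions Optional named character vector (`"greater"` /
#'   `"less"`) per metric; default `"greater"` for all.
#' @return Tibble `metric, auc, optimal_threshold, sensitivity,
#'   specificity, youden_j`.
#' @export
sectioningReport <- function(scored,
                             metrics = c("avi", "pvi", "rotation_deg",
                                         "translation_pct_epw",
                                         "translation_mm",
                                         "segment_angle_diff_deg",
                                         "rotation_diff_deg"),
                             intact_label = "intact",
                             stage = NULL,
                             directions = NULL) {
  stopifnot("condition" %in% names(scored))
  d <- scored
  if (!is.null(stage)) {
    d <- d[d$condition %in% c(intact_label, stage), , drop = FALSE]
  }
  labels <- d$condition != intact_label
  rows <- lapply(metrics, function(m) {
    if (!m %in% names(d)) {
      warning("metric ", m, " absent from scores; skipped")
      return(NULL)
    }
    dir <- if (!is.null(directions) && m %in% names(directions))
      directions[[m]] else "greater"
    keep <- is.finite(d[[m]])
    r <- rocCurve(d[[m]][keep], labels[keep], direction = dir)
    tibble::tibble(metric = m, auc = r$auc,
                   optimal_threshold = r$youden$threshold,
                   sensitivity = r$youden$sensitivity,
                   specificity = r$youden$specificity,
                   youden_j = r$youden$j)
  })
  do.call(rbind, rows)
}
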