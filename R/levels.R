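#' Cervical vertebra and motion-segment labels
#'
#' The subaxial cervical spine is analyzed from C2 down to C7, giving five
#' motion segments (level pairs) C2-C3 through C6-C7.
#'
#' @return `cervicalLevels()` returns the six vertebra labels;
#'   `cervicalLevelPairs()` the five motion-segment labels, cranial to caudal.
#' @export
cervicalLevels <- function() {
  c("C2", "C3", "C4", "C5", "C6", "C7")
}

#' @rdname cervicalLevels
#' @export
cervicalLevelPairs <- function() {
  lv <- cervicalLevels()
  paste(lv[-length(lv)], lv[-1], sep = "-")
}

# corner roles, canonical order (anterior/posterior x superior/inferior)
cornerRoles <- function() c("AS", "AI", "PS", "PI")

#' Default per-level average endplate widths in millimetres
#'
#' Used to convert translation from percent endplate width to millimetres.
#' Each cervical level is assigned a population-average superior endplate
#' width of the inferior vertebra (mm), derived from calibrated radiographic
#' measurements; values are user-overridable wherever they are consumed.
#'
#' @return Named numeric vector over the five level pairs, in mm.
#' @export
defaultEndplateWidthsMm <- function() {
  stats::setNames(c(14.9, 14.9, 14.9, 15.8, 16.7), cervicalLevelPairs())
}

#' Default abnormality thresholds
#'
#' All thresholds applied by the scoring module, collected in one list so a
#' fitted [NormativeReference][fitReference] carries them and users can
#' override any of them:
#' \describe{
#'   \item{index_limit}{TI/AVI/PVI (and |SDH|) normal limit; values in
#'     \[-index_limit, +index_limit\] are within normal limits (default 2).}
#'   \item{rotation_diff_limit}{abnormal when the maximum rotation difference
#'     vs adjacent levels exceeds this (default 11 degrees).}
#'   \item{angle_diff_limit}{abnormal when the maximum flexion segment-angle
#'     difference vs adjacent levels exceeds this (default 11 degrees).}
#'   \item{translation_limit}{abnormal when |translation| exceeds this
#'     (default 20 percent endplate width).}
#'   \item{translation_mm_limit}{legacy 3.5 mm criterion; present but
#'     disabled by default (`use_mm_criterion = FALSE`) because it assumes
#'     ~30% radiographic magnification absent from magnification-free
#'     measurements.}
#'   \item{min_rotation}{segments rotating less than this are excluded from
#'     reference fitting and from scoring (default 5 degrees).}
#'   \item{effort_min_total}{exam-level effort filter: minimum total C2-C7
#'     rotation (default 60 degrees).}
#' }
#'
#' @return Named list of thresholds.
#' @export
defaultThresholds <- function() {
  list(
    index_limit = 2,
    rotation_diff_limit = 11,
    angle_diff_limit = 11,
    translation_limit = 20,
    translation_mm_limit = 3.5,
    use_mm_criterion = FALSE,
    min_rotation = 5,
    effort_min_total = 60
  )
}

#' Upper limit of the 95% reference interval
#'
#' One-sided normal-theory upper limit `mean + 1.96 * sd`, as used for the
#' per-level reference tables.
#'
#' @param mean,sd Sample mean and standard deviation (vectorized).
#' @return Numeric upper limit(s).
#' @export
upperLimit95 <- function(mean, sd) {
  stopifnot(all(sd >= 0, na.rm = TRUE))
  mean + 1.96 * sd
}

# neighbors of a level pair among the five segments
adjacentPairs <- function(pair) {
  pairs <- cervicalLevelPairs()
  i <- match(pair, pairs)
  if (is.na(i)) stop("unknown level pair: ", pair)
  pairs[c(i - 1L, i + 1L)[c(i - 1L, i + 1L) >= 1L & c(i - 1L, i + 1L) <= length(pairs)]]
}
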