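#' Construct landmarks for one vertebra
#'
#' Four corner landmarks describe one vertebral body on one radiograph in
#' image-plane coordinates (x increases rightward, y increases *downward*,
#' the usual image convention; units may be pixels of unknown magnification).
#' Corner roles are `AS` (anterior-superior), `AI` (anterior-inferior),
#' `PS` (posterior-superior), `PI` (posterior-inferior).
#'
#' @param level Vertebra label, one of `cervicalLevels()`.
#' @param corners 4 x 2 numeric matrix with rownames `AS`, `AI`, `PS`, `PI`
#'   and columns x, y; or a named list of length-2 numeric vectors.
#' @return An object of class `vertebra_landmarks`.
#' @export
vertebraLandmarks <- function(level, corners) {
  if (!level %in% cervicalLevels()) {
    stop("invalid vertebra level: ", level)
  }
  if (is.list(corners)) {
    m <- do.call(rbind, corners[cornerRoles()])
    rownames(m) <- cornerRoles()
    corners <- m
  }
  v <- structure(list(level = level, corners = corners),
                 class = "vertebra_landmarks")
  validateVertebra(v)
  v
}

validateVertebra <- function(v) {
  m <- v$corners
  if (!is.matrix(m) || !all(cornerRoles() %in% rownames(m)) || ncol(m) != 2L) {
    stop("vertebra ", v$level, ": corners must be a 4x2 matrix with rows ",
         paste(cornerRoles(), collapse = ", "))
  }
  m <- m[cornerRoles(), , drop = FALSE]
  if (!all(is.finite(m))) {
    stop("vertebra ", v$level, ": non-finite landmark coordinates")
  }
  d <- as.matrix(stats::dist(m))
  if (any(d[upper.tri(d)] < .Machine$double.eps^0.5)) {
    stop("vertebra ", v$level, ": corner landmarks must be pairwise distinct")
  }
  if (sqrt(sum((m["AS", ] - m["PS", ])^2)) <= 0 ||
      sqrt(sum((m["AI", ] - m["PI", ])^2)) <= 0) {
    stop("vertebra ", v$level, ": endplate width must be positive")
  }
  invisible(v)
}

#' @export
print.vertebra_landmarks <- function(x, ...) {
  cat("<vertebra_landmarks> ", x$level, "\n", sep = "")
  print(round(x$corners[cornerRoles(), ], 3))
  invisible(x)
}

#' Construct landmarks for one radiograph (one phase)
#'
#' @param phase `"flexion"` or `"extension"`.
#' @param vertebrae List of [vertebraLandmarks()] objects; at most one per
#'   level.  Levels need not be contiguous -- vertebrae obscured by shoulder
#'   scatter or field-of-view limits are simply absent.
#' @param facing `"left"` or `"right"`: the screen direction the patient
#'   faces, i.e. which way is anatomically anterior.
#' @return An object of class `radiograph_landmarks`.
#' @export
radiographLandmarks <- function(phase = c("flexion", "extension"),
                                vertebrae = list(),
                                facing = c("right", "left")) {
  phase <- match.arg(phase)
  facing <- match.arg(facing)
  lv <- vapply(vertebrae, function(v) v$level, character(1))
  if (anyDuplicated(lv)) {
    stop("duplicate vertebra level in ", phase, " phase: ",
         paste(unique(lv[duplicated(lv)]), collapse = ", "))
  }
  names(vertebrae) <- lv
  ord <- order(match(lv, cervicalLevels()))
  structure(list(phase = phase, vertebrae = vertebrae[ord], facing = facing),
            class = "radiograph_landmarks")
}

#' Construct a flexion-extension exam
#'
#' A complete exam pairs one flexion and one extension radiograph, with
#' optional per-level degeneration grades (Kellgren-Lawrence ordinals, keyed
#' by level pair) and an optional condition label (e.g. intact vs a ligament
#' sectioning stage for cadaveric experiments).
#'
#' @param exam_id Opaque identifier string.
#' @param flexion,extension [radiographLandmarks()] objects of the matching
#'   phase.
#' @param degeneration Optional named numeric/integer vector of grades keyed
#'   by level pair (e.g. `c("C4-C5" = 2)`).
#' @param condition Optional condition label string.
#' @return An object of class `exam_landmarks`.
#' @export
examLandmarks <- function(exam_id, flexion, extension,
                          degeneration = NULL, condition = NULL) {
  stopifnot(inherits(flexion, "radiograph_landmarks"),
            inherits(extension, "radiograph_landmarks"))
  if (flexion$phase != "flexion" || extension$phase != "extension") {
    stop("exam ", exam_id, ": phases of the two radiographs must be ",
         "flexion and extension respectively")
  }
  if (length(flexion$vertebrae) == 0L || length(extension$vertebrae) == 0L) {
    stop("exam ", exam_id, ": both phases must contain at least one vertebra")
  }
  if (!is.null(degeneration)) {
    bad <- setdiff(names(degeneration), cervicalLevelPairs())
    if (length(bad)) stop("exam ", exam_id, ": unknown level pair in ",
                          "degeneration grades: ", paste(bad, collapse = ", "))
  }
  structure(list(exam_id = as.character(exam_id),
                 flexion = flexion, extension = extension,
                 degeneration = degeneration,
                 condition = condition),
            class = "exam_landmarks")
}

#' @export
print.exam_landmarks <- function(x, ...) {
  cat("<exam_landmarks> ", x$exam_id, "\n", sep = "")
  cat("  flexion:   ", paste(names(x$flexion$vertebrae), collapse = " "),
      " (facing ", x$flexion$facing, ")\n", sep = "")
  cat("  extension: ", paste(names(x$extension$vertebrae), collapse = " "),
      "\n", sep = "")
  if (!is.null(x$condition)) cat("  condition: ", x$condition, "\n", sep = "")
  invisible(x)
}

#' Level pairs measurable in an exam
#'
#' A motion segment is computable iff both of its vertebrae are present in
#' both phases (missing data are handled per level, not per exam).
#'
#' @param exam An [examLandmarks()] object.
#' @return Character vector of available level pairs.
#' @export
availableSegments <- function(exam) {
  lv <- intersect(names(exam$flexion$vertebrae), names(exam$extension$vertebrae))
  pairs <- cervicalLevelPairs()
  sup <- sub("-.*", "", pairs)
  inf <- sub(".*-", "", pairs)
  pairs[sup %in% lv & inf %in% lv]
}
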