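#' Read a flexion-extension landmark exam from disk
#'
#' Two formats are supported, detected from the file extension:
#' \describe{
#'   \item{JSON}{`{"exam_id": str, "facing": "left"|"right",
#'     "flexion": {"C2": {"AS": [x,y], "AI": [x,y], "PS": [x,y],
#'     "PI": [x,y]}, ...}, "extension": {...},
#'     "degeneration": {"C2-C3": int, ...}, "condition": str|null}`}
#'   \item{CSV (long form)}{columns `exam_id, phase, level, corner, x, y`,
#'     one exam per file; `facing`/`condition` may be supplied via the
#'     `facing` and `condition` arguments since the flat table has no slot
#'     for them.}
#' }
#'
#' Vertebrae with unparseable (non-numeric or non-finite) coordinates are
#' dropped with a warning; structural schema violations (missing phase,
#' duplicate level within a phase, fewer than four corners for a listed
#' vertebra) are errors naming the exam and level.
#'
#' @param path File path (`.json` or `.csv`).
#' @param facing,condition Used for the CSV dialect only (JSON carries both).
#' @return A validated [examLandmarks()] object.
#' @export
readExam <- function(path, facing = "right", condition = NULL) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readExamCsv(path, facing = facing, condition = condition)
  } else {
    readExamJson(path)
  }
}

readExamJson <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyMatrix = FALSE,
                          simplifyDataFrame = FALSE)
  exam_id <- x[["exam_id"]]
  if (is.null(exam_id)) stop("landmark file ", path, ": missing exam_id")
  facing <- x[["facing"]]
  if (is.null(facing) || !facing %in% c("left", "right")) {
    stop("exam ", exam_id, ": facing must be \"left\" or \"right\"")
  }
  for (ph in c("flexion", "extension")) {
    if (is.null(x[[ph]])) stop("exam ", exam_id, ": missing phase ", ph)
  }
  parsePhase <- function(ph) {
    entries <- x[[ph]]
    if (anyDuplicated(names(entries))) {
      stop("exam ", exam_id, ": duplicate level in ", ph, " phase")
    }
    vv <- list()
    for (lev in names(entries)) {
      e <- entries[[lev]]
      if (!all(cornerRoles() %in% names(e))) {
        stop("exam ", exam_id, " level ", lev, " (", ph, "): ",
             "all four corners AS, AI, PS, PI are required")
      }
      m <- try(suppressWarnings(
        do.call(rbind, lapply(e[cornerRoles()], as.numeric))),
        silent = TRUE)
      if (inherits(m, "try-error") || !is.numeric(m) || ncol(m) != 2L ||
          !all(is.finite(m))) {
        warning("exam ", exam_id, " level ", lev, " (", ph, "): ",
                "unparseable coordinates; vertebra dropped")
        next
      }
      rownames(m) <- cornerRoles()
      vv[[lev]] <- vertebraLandmarks(lev, m)
    }
    radiographLandmarks(ph, vv, facing = facing)
  }
  deg <- NULL
  if (!is.null(x[["degeneration"]]) && length(x[["degeneration"]])) {
    deg <- vapply(x[["degeneration"]], as.numeric, numeric(1))
  }
  cond <- x[["condition"]]
  if (is.null(cond) || length(cond) == 0L) cond <- NULL
  examLandmarks(exam_id, parsePhase("flexion"), parsePhase("extension"),
                degeneration = deg, condition = cond)
}

readExamCsv <- function(path, facing = "right", condition = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("exam_id", "phase", "level", "corner", "x", "y")
  if (!all(need %in% names(d))) {
    stop("landmark CSV ", path, ": requires columns ",
         paste(need, collapse = ", "))
  }
  ids <- unique(d$exam_id)
  if (length(ids) != 1L) {
    stop("landmark CSV ", path, ": expected a single exam_id, found ",
         length(ids))
  }
  mk <- function(ph) {
    dd <- d[d$phase == ph, , drop = FALSE]
    if (nrow(dd) == 0L) stop("exam ", ids, ": missing phase ", ph)
    vv <- list()
    for (lev in unique(dd$level)) {
      e <- dd[dd$level == lev, , drop = FALSE]
      if (anyDuplicated(e$corner)) {
        stop("exam ", ids, ": duplicate corners for level ", lev,
             " in ", ph, " phase")
      }
      if (!all(cornerRoles() %in% e$corner)) {
        stop("exam ", ids, " level ", lev, " (", ph, "): ",
             "all four corners AS, AI, PS, PI are required")
      }
      m <- as.matrix(e[match(cornerRoles(), e$corner), c("x", "y")])
      dimnames(m) <- list(cornerRoles(), NULL)
      if (!all(is.finite(m))) {
        warning("exam ", ids, " level ", lev, " (", ph, "): ",
                "unparseable coordinates; vertebra dropped")
        next
      }
      vv[[lev]] <- vertebraLandmarks(lev, m)
    }
    radiographLandmarks(ph, vv, facing = facing)
  }
  examLandmarks(ids, mk("flexion"), mk("extension"), condition = condition)
}

#' Write a flexion-extension exam as canonical JSON
#'
#' Output is canonical -- levels sorted cranial to caudal, corners in fixed
#' `AS, AI, PS, PI` order, coordinates at 17 significant digits -- so two
#' writes of the same exam are byte-identical and a read-write round trip is
#' the identity to full double precision.
#'
#' @param exam An [examLandmarks()] object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeExam <- function(exam, path) {
  stopifnot(inherits(exam, "exam_landmarks"))
  if (length(exam$flexion$vertebrae) == 0L ||
      length(exam$extension$vertebrae) == 0L) {
    stop("exam ", exam$exam_id, ": both phases must contain vertebrae")
  }
  phaseList <- function(rg) {
    lv <- names(rg$vertebrae)
    lv <- lv[order(match(lv, cervicalLevels()))]
    out <- list()
    for (lev in lv) {
      m <- rg$vertebrae[[lev]]$corners
      out[[lev]] <- stats::setNames(
        lapply(cornerRoles(), function(r) as.numeric(m[r, ])), cornerRoles())
    }
    out
  }
  deg <- exam$degeneration
  if (!is.null(deg)) {
    deg <- as.list(deg[order(match(names(deg), cervicalLevelPairs()))])
  }
  obj <- list(
    exam_id = exam$exam_id,
    facing = exam$flexion$facing,
    flexion = phaseList(exam$flexion),
    extension = phaseList(exam$extension),
    degeneration = deg,
    condition = exam$condition
  )
  json <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE,
                           null = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read every landmark exam in a directory
#'
#' @param dir Directory containing `.json` landmark exams.
#' @return List of [examLandmarks()] objects, named by exam id.
#' @export
readExamDir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  exams <- lapply(files, readExam)
  names(exams) <- vapply(exams, function(e) e$exam_id, character(1))
  exams
}
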