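# Geometric primitives on vertebral corner landmarks.
#
# All coordinates are image-plane (x right, y down).  Corner labels carry the
# anatomy, so anterior directions come from the labels; the `facing` flag is
# needed only where a *signed* angle must be oriented anatomically (extension,
# i.e. anterior opening, positive) because mirroring the scene flips the
# screen sense of rotation.

facingSign <- function(facing) if (identical(facing, "left")) -1 else 1

#' Endplate line of a vertebra
#'
#' The line through the two corners of one endplate, directed from the
#' posterior to the anterior corner.
#'
#' @param v A [vertebraLandmarks()] object.
#' @param side `"superior"` or `"inferior"`.
#' @param facing Patient orientation flag (kept for interface symmetry; the
#'   direction itself follows the anatomical corner labels).
#' @return List with `origin` (posterior corner, length-2), `direction`
#'   (unit vector posterior to anterior) and `width` (corner distance).
#' @export
endplate <- function(v, side = c("superior", "inferior"), facing = "right") {
  side <- match.arg(side)
  post <- if (side == "superior") "PS" else "PI"
  ant  <- if (side == "superior") "AS" else "AI"
  p <- v$corners[post, ]
  a <- v$corners[ant, ]
  d <- a - p
  w <- sqrt(sum(d^2))
  if (w <= .Machine$double.eps^0.5) {
    stop("vertebra ", v$level, ": zero-width ", side, " endplate")
  }
  list(origin = p, direction = d / w, width = w)
}

# signed angle (degrees) from direction u1 to direction u2, positive when u2
# is rotated toward the anatomically superior side relative to u1
signedAngleDeg <- function(u1, u2, facing) {
  fx <- facingSign(facing)
  cross <- u1[1] * u2[2] - u1[2] * u2[1]
  dot <- sum(u1 * u2)
  atan2(-fx * cross, dot) * 180 / pi
}

#' Disc angle of a motion segment in one pose
#'
#' Signed angle between the inferior endplate of the superior vertebra and
#' the superior endplate of the inferior vertebra.  Anterior disc opening
#' (extension posture) is positive.
#'
#' @param superior,inferior [vertebraLandmarks()] of adjacent levels.
#' @param facing Patient orientation of the radiograph.
#' @return Angle in degrees.
#' @export
discAngle <- function(superior, inferior, facing = "right") {
  checkAdjacent(superior, inferior)
  u_inf <- endplate(inferior, "superior", facing)$direction
  u_sup <- endplate(superior, "inferior", facing)$direction
  signedAngleDeg(u_inf, u_sup, facing)
}

#' Segment angle (AMA convention) of a motion segment in one pose
#'
#' Signed angle between the inferior endplate of the superior vertebra and
#' the inferior endplate of the inferior vertebra, with the same sign
#' convention as [discAngle()].  Depends only on the two inferior endplates.
#'
#' @inheritParams discAngle
#' @return Angle in degrees.
#' @export
segmentAngle <- function(superior, inferior, facing = "right") {
  checkAdjacent(superior, inferior)
  u_inf <- endplate(inferior, "inferior", facing)$direction
  u_sup <- endplate(superior, "inferior", facing)$direction
  signedAngleDeg(u_inf, u_sup, facing)
}

checkAdjacent <- function(superior, inferior) {
  lv <- cervicalLevels()
  i <- match(superior$level, lv)
  j <- match(inferior$level, lv)
  if (is.na(i) || is.na(j) || j != i + 1L) {
    stop("vertebrae ", superior$level, " and ", inferior$level,
         " are not an adjacent superior/inferior pair")
  }
  invisible(TRUE)
}

#' Intervertebral rotation from a pair of disc angles
#'
#' Difference in disc angle between the extension and flexion poses
#' (extension minus flexion), so that normal full-effort motion is positive.
#'
#' @param flex_angle,ext_angle Disc angles (degrees) of the same segment in
#'   flexion and extension.
#' @return Rotation in degrees.
#' @export
intervertebralRotation <- function(flex_angle, ext_angle) {
  ext_angle - flex_angle
}

#' Least-squares similarity registration of 2-D point sets
#'
#' Fits the rotation + uniform scale + translation minimizing the summed
#' squared distance from the transformed `from` points to the `to` points
#' (closed form via complex linear least squares; no reflection).
#'
#' @param from,to n x 2 matrices of corresponding points (n >= 2).
#' @return List with `transform(p)` applying the map to an n x 2 matrix or a
#'   length-2 point, plus `scale`, `angle_rad` (screen-coordinate rotation)
#'   and `rmse`.
#' @export
similarityFit <- function(from, to) {
  stopifnot(nrow(from) == nrow(to), ncol(from) == 2L, ncol(to) == 2L)
  zf <- complex(real = from[, 1], imaginary = from[, 2])
  zt <- complex(real = to[, 1], imaginary = to[, 2])
  mf <- mean(zf); mt <- mean(zt)
  zfc <- zf - mf
  denom <- sum(Mod(zfc)^2)
  spread <- sqrt(denom / length(zf))
  if (spread <= 1e-9 * max(1, Mod(mf))) {
    stop("degenerate registration: source landmarks are coincident")
  }
  # collinear point sets leave the fit reflection-ambiguous; reject
  sv <- svd(scale(from, scale = FALSE))$d
  if (sv[2] <= 1e-9 * sv[1]) {
    stop("degenerate registration: collinear landmarks")
  }
  a <- sum(Conj(zfc) * (zt - mt)) / denom
  b <- mt - a * mf
  transform <- function(p) {
    if (is.null(dim(p))) p <- matrix(p, ncol = 2L)
    z <- a * complex(real = p[, 1], imaginary = p[, 2]) + b
    out <- cbind(Re(z), Im(z))
    if (nrow(out) == 1L) out <- drop(out)
    out
  }
  resid <- a * zf + b - zt
  list(transform = transform, scale = Mod(a), angle_rad = Arg(a),
       rmse = sqrt(mean(Mod(resid)^2)))
}

#' Intervertebral translation in percent endplate width
#'
#' The extension pose is registered onto the flexion pose by a least-squares
#' similarity transform of the *inferior* vertebra's four corners; the
#' displacement of the superior vertebra's posterior-inferior corner between
#' the phases is then projected onto the flexion inferior vertebra's superior
#' endplate direction and normalized by that endplate's width.  Anterior
#' displacement from extension to flexion is positive.  The construction is
#' invariant to global similarity transforms of either radiograph.
#'
#' @param sup_flex,sup_ext Superior vertebra in flexion and extension.
#' @param inf_flex,inf_ext Inferior vertebra in flexion and extension.
#' @param facing Patient orientation (interface symmetry).
#' @return Translation in percent endplate width (signed).
#' @export
intervertebralTranslation <- function(sup_flex, sup_ext, inf_flex, inf_ext,
                                      facing = "right") {
  checkAdjacent(sup_flex, inf_flex)
  fit <- similarityFit(inf_ext$corners[cornerRoles(), ],
                       inf_flex$corners[cornerRoles(), ])
  pi_ext_mapped <- fit$transform(sup_ext$corners["PI", ])
  delta <- sup_flex$corners["PI", ] - pi_ext_mapped
  ep <- endplate(inf_flex, "superior", facing)
  100 * sum(delta * ep$direction) / ep$width
}

#' Anterior and posterior disc heights in percent endplate width
#'
#' Corner-to-corner Euclidean distances: anterior-inferior corner of the
#' superior vertebra to anterior-superior corner of the inferior vertebra
#' (`dh_A`), and the posterior analogue (`dh_P`), both normalized by the
#' inferior vertebra's superior endplate width.
#'
#' @inheritParams discAngle
#' @return Named numeric vector `c(dh_A = , dh_P = )` in percent endplate
#'   width.
#' @export
discHeights <- function(superior, inferior, facing = "right") {
  checkAdjacent(superior, inferior)
  w <- endplate(inferior, "superior", facing)$width
  dh_a <- sqrt(sum((superior$corners["AI", ] - inferior$corners["AS", ])^2))
  dh_p <- sqrt(sum((superior$corners["PI", ] - inferior$corners["PS", ])^2))
  c(dh_A = 100 * dh_a / w, dh_P = 100 * dh_p / w)
}

# orientation change (degrees) of one vertebra from flexion to extension,
# positive toward extension (anterior up); rigid-body angle from the
# similarity registration of its own four corners
vertebraRotationChange <- function(v_flex, v_ext, facing = "right") {
  fit <- similarityFit(v_flex$corners[cornerRoles(), ],
                       v_ext$corners[cornerRoles(), ])
  -facingSign(facing) * fit$angle_rad * 180 / pi
}
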