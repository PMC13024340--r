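# Synthetic cohorts with the statistical structure the method assumes:
# per-level Gaussian rotation, translation linear in rotation (per level),
# disc-height change linear in rotation (pooled across levels), plus
# injectable injury effects emulating sequential ligament sectioning.

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the asymptomatic reference-cohort structure: per-level
#' rotation means/SDs and translation means/SDs with the per-level
#' rotation-translation coupling implied by the published R-squared values
#' (slope = trans_sd * sqrt(R2) / rot_sd, noise = trans_sd * sqrt(1 - R2)),
#' pooled rotation-dependent disc-widening lines, and disc-height baselines
#' placed in a plausible 10-25 percent-endplate-width band.  The injury
#' block defines cumulative per-stage shifts for the sectioning experiment:
#' rotation increases with sectioning, disc opening increases beyond what
#' the shifted rotation predicts, and translation is generated from the
#' *pre-injury* rotation (facet joints preserved), so translation barely
#' changes -- the pattern seen in cadaveric sectioning.
#'
#' @param effort Multiplier on per-level rotation means (1 = full-effort
#'   asymptomatic motion; ~0.6 emulates the reduced effort of symptomatic
#'   cohorts).
#' @param rddw_anterior,rddw_posterior Lists `slope, intercept, noise_sd`
#'   for the pooled disc-widening lines (%EPW per degree).
#' @param adh_base_mean,adh_base_sd,pdh_base_mean,pdh_base_sd Baseline
#'   (rotation-independent) anterior/posterior disc-height centers (%EPW).
#' @param seg_angle_sd Between-subject SD of flexion segment angles (deg).
#' @param epw_mm Per-level endplate widths in mm,
#'   [defaultEndplateWidthsMm()].
#' @param injury List with `stages` (labels), cumulative `rotation_shift`,
#'   `dadh_shift`, `dpdh_shift`, `translation_shift` per stage, and
#'   `target_level`.
#' @return Object of class `generator_config` with a per-level `levels`
#'   tibble and the pooled/injury blocks.
#' @export
generatorConfig <- function(effort = 1,
                            rddw_anterior = list(slope = 0.8, intercept = 0,
                                                 noise_sd = 1.55),
                            rddw_posterior = list(slope = 0.6, intercept = 0,
                                                  noise_sd = 1.30),
                            adh_base_mean = 20, adh_base_sd = 2,
                            pdh_base_mean = 18, pdh_base_sd = 1.5,
                            seg_angle_sd = 2.8,
                            epw_mm = defaultEndplateWidthsMm(),
                            injury = list(
                              stages = c("ligaments", "disc", "uvj"),
                              rotation_shift = c(2, 4, 6),
                              dadh_shift = c(5, 8, 11),
                              dpdh_shift = c(4, 6, 9),
                              translation_shift = c(0, 0, 0),
                              target_level = "C4-C5")) {
  stopifnot(effort > 0, rddw_anterior$noise_sd >= 0,
            rddw_posterior$noise_sd >= 0)
  lv <- tibble::tibble(
    level = cervicalLevelPairs(),
    rot_mean = c(8.7, 14.1, 17.9, 19.1, 16.5),
    rot_sd = c(2.8, 3.4, 3.2, 4.5, 4.7),
    trans_mean = c(12.1, 15.4, 18.1, 15.2, 9.0),
    trans_sd = c(4.7, 4.7, 4.5, 4.5, 3.1),
    r2_rdt = c(0.56, 0.48, 0.30, 0.48, 0.56),
    seg_angle_mean = c(-1, 1, 3, 2, 0),
    seg_angle_sd = seg_angle_sd,
    adh_base_mean = adh_base_mean, adh_base_sd = adh_base_sd,
    pdh_base_mean = pdh_base_mean, pdh_base_sd = pdh_base_sd
  )
  lv$rdt_slope <- lv$trans_sd * sqrt(lv$r2_rdt) / lv$rot_sd
  lv$rdt_noise_sd <- lv$trans_sd * sqrt(1 - lv$r2_rdt)
  lv$rdt_intercept <- lv$trans_mean - lv$rdt_slope * lv$rot_mean
  structure(list(levels = lv, effort = effort,
                 rddw_anterior = rddw_anterior,
                 rddw_posterior = rddw_posterior,
                 epw_mm = epw_mm, injury = injury),
            class = "generator_config")
}

# draw metric rows for one exam; injury = NULL or list(level, rotation_shift,
# dadh_shift, dpdh_shift, translation_shift)
drawExamRows <- function(cfg, exam_id, injury = NULL) {
  lv <- cfg$levels
  k <- nrow(lv)
  rot0 <- stats::rnorm(k, lv$rot_mean * cfg$effort, lv$rot_sd)
  rot <- rot0
  trans <- lv$rdt_slope * rot0 + lv$rdt_intercept +
    stats::rnorm(k, 0, lv$rdt_noise_sd)
  if (!is.null(injury)) {
    i <- match(injury$level, lv$level)
    rot[i] <- rot0[i] + injury$rotation_shift
    trans[i] <- trans[i] + injury$translation_shift
  }
  a <- cfg$rddw_anterior; p <- cfg$rddw_posterior
  dadh <- a$slope * rot + a$intercept + stats::rnorm(k, 0, a$noise_sd)
  dpdh <- p$slope * rot + p$intercept + stats::rnorm(k, 0, p$noise_sd)
  if (!is.null(injury)) {
    i <- match(injury$level, lv$level)
    dadh[i] <- dadh[i] + injury$dadh_shift
    dpdh[i] <- dpdh[i] + injury$dpdh_shift
  }
  base_a <- stats::rnorm(k, lv$adh_base_mean, lv$adh_base_sd)
  base_p <- stats::rnorm(k, lv$pdh_base_mean, lv$pdh_base_sd)
  seg <- stats::rnorm(k, lv$seg_angle_mean, lv$seg_angle_sd)
  rotv <- stats::setNames(rot, lv$level)
  segv <- stats::setNames(seg, lv$level)
  total <- sum(rot)
  tibble::tibble(
    exam_id = exam_id,
    level = lv$level,
    rotation_deg = rot,
    translation_pct_epw = trans,
    translation_mm = trans / 100 * cfg$epw_mm[lv$level],
    adh_flex = base_a - dadh / 2,
    adh_ext = base_a + dadh / 2,
    pdh_flex = base_p + dpdh / 2,
    pdh_ext = base_p - dpdh / 2,
    avg_dh = (base_a + base_p) / 2,
    disc_angle_flex = -0.45 * rot,
    disc_angle_ext = 0.55 * rot,
    segment_angle_flex = seg,
    segment_angle_ext = seg + rot,
    rotation_diff_deg = vapply(lv$level, function(q)
      adjacentLevelDifference(rotv, q), numeric(1)),
    segment_angle_diff_deg = vapply(lv$level, function(q)
      adjacentLevelDifference(segv, q), numeric(1)),
    total_c2c7_rotation_deg = total,
    rotation_pct_c2c7 = 100 * rot / total,
    degeneration = NA_real_,
    condition = NA_character_
  )
}

#' Generate a synthetic metric-level cohort
#'
#' Draws `n` flexion-extension exams (all five segments each) from the
#' configured model: per-level Gaussian rotation scaled by the effort
#' multiplier, translation on the per-level rotation-dependent line plus
#' Gaussian noise, anterior/posterior disc openings on the pooled lines,
#' and baseline disc heights decomposed so that
#' `adh_ext - adh_flex` equals the drawn anterior opening (and
#' `pdh_flex - pdh_ext` the posterior one).  With all noise SDs zero every
#' point lies exactly on the configured lines.
#'
#' @param cfg A [generatorConfig()].
#' @param n Number of exams (subjects).
#' @param seed Optional integer seed; fixed seed gives identical output.
#' @param id_prefix Prefix for generated exam ids.
#' @return Segment-level tibble in the [examMetrics()] column layout; the
#'   same table is attached as attribute `ground_truth`.
#' @export
generateMetricCohort <- function(cfg, n = 341, seed = NULL,
                                 id_prefix = "sim") {
  stopifnot(inherits(cfg, "generator_config"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- do.call(rbind, lapply(seq_len(n), function(i)
    drawExamRows(cfg, sprintf("%s%05d", id_prefix, i))))
  attr(out, "ground_truth") <- out
  out
}

# Solve the pose of one superior vertebra in the local frame of the inferior
# vertebra's superior endplate (origin at posterior corner, +x anterior
# along the endplate, +y up).  Unknowns: the bearing of the posterior-
# inferior corner in each phase (psi_f, psi_e), the superior vertebra's
# endplate width (ws, relative to W) and a common disc-angle offset (delta)
# added to both phases -- rotation, being the phase difference, is exact by
# construction regardless of delta.  Three constraints (translation and the
# two anterior disc heights) in four unknowns: solved by minimum-norm
# Gauss-Newton from a nominal symmetric pose, so the nearest realizable
# pose is found.  Returns corner coordinates and the solved width.
solveSegmentPose <- function(W, rotation_deg, translation_pct, dha_f, dha_e,
                             dhp_f, dhp_e, phi_flex_frac = 0.45,
                             label = "segment") {
  dims <- c(dha_f, dha_e, dhp_f, dhp_e) / 100  # in units of W
  if (any(dims <= 0)) {
    stop("infeasible geometry at ", label, ": disc heights must be positive")
  }
  dhAf <- dims[1]; dhAe <- dims[2]; dhPf <- dims[3]; dhPe <- dims[4]
  T_rel <- translation_pct / 100
  rot <- rotation_deg * pi / 180
  phi0 <- -phi_flex_frac * rot
  qa <- c(1, 0)
  fun <- function(z) {
    psi_f <- z[1]; psi_e <- z[2]; ws <- z[3]; delta <- z[4]
    phi_f <- phi0 + delta
    phi_e <- phi_f + rot
    pf <- dhPf * c(sin(psi_f), cos(psi_f))
    pe <- dhPe * c(sin(psi_e), cos(psi_e))
    c(pf[1] - pe[1] - T_rel,
      sqrt(sum((pf + ws * c(cos(phi_f), sin(phi_f)) - qa)^2)) - dhAf,
      sqrt(sum((pe + ws * c(cos(phi_e), sin(phi_e)) - qa)^2)) - dhAe)
  }
  tol <- 1e-11
  newton <- function(z) {
    for (it in seq_len(100)) {
      F0 <- fun(z)
      n0 <- max(abs(F0))
      if (n0 < tol) return(z)
      J <- matrix(0, 3, 4)
      h <- 1e-7
      for (j in 1:4) {
        zj <- z; zj[j] <- zj[j] + h
        J[, j] <- (fun(zj) - F0) / h
      }
      sv <- svd(J)
      if (sv$d[3] < 1e-12 * sv$d[1]) return(NULL)
      step <- sv$v %*% ((t(sv$u) %*% F0) / sv$d)  # minimum-norm solution
      lam <- 1
      improved <- FALSE
      while (lam >= 1e-8) {
        zn <- z - lam * step
        if (zn[3] > 0.02 && max(abs(fun(zn))) < n0) {
          improved <- TRUE
          break
        }
        lam <- lam / 2
      }
      if (!improved) return(NULL)
      z <- zn
    }
    if (max(abs(fun(z))) < tol) z else NULL
  }
  clamp <- function(x) max(-0.999, min(0.999, x))
  inits <- list(
    c(asin(clamp(T_rel / 2 / dhPf)), asin(clamp(-T_rel / 2 / dhPe)),
      0.95, 0),
    c(0, 0, 1, 0),
    c(asin(clamp(T_rel / dhPf)), 0, 0.9, 0.05),
    c(0, asin(clamp(-T_rel / dhPe)), 1.05, -0.05))
  sol_z <- NULL
  for (z0 in inits) {
    sol_z <- newton(z0)
    if (!is.null(sol_z)) break
  }
  if (is.null(sol_z)) {
    # deterministic wide multi-start over the full angular range: cheap
    # Newton from each grid point first, then least-squares descent + polish
    grid <- expand.grid(psi_f = seq(-2.4, 2.4, by = 0.8),
                        psi_e = seq(-2.4, 2.4, by = 0.8),
                        ws = c(0.7, 1.3))
    starts <- lapply(seq_len(nrow(grid)), function(k)
      c(grid$psi_f[k], grid$psi_e[k], grid$ws[k], 0))
    for (z0 in starts) {
      sol_z <- newton(z0)
      if (!is.null(sol_z)) break
    }
    if (is.null(sol_z)) {
      obj <- function(z) sum(fun(z)^2)
      for (z0 in starts) {
        o <- stats::optim(z0, obj, method = "BFGS",
                          control = list(maxit = 400, reltol = 1e-14))
        sol_z <- newton(o$par)
        if (!is.null(sol_z)) break
      }
    }
  }
  if (is.null(sol_z)) {
    stop("infeasible geometry at ", label,
         ": no pose realizes the prescribed metrics")
  }
  psi_f <- sol_z[1]; psi_e <- sol_z[2]; ws <- sol_z[3]
  phi_f <- phi0 + sol_z[4]; phi_e <- phi_f + rot
  mk <- function(psi, phi, dhP) {
    p <- W * dhP * c(sin(psi), cos(psi))
    d <- c(cos(phi), sin(phi))
    e <- c(-sin(phi), cos(phi))
    wa <- W * ws
    hs <- 0.7 * wa
    list(PI = p, AI = p + wa * d, PS = p + hs * e, AS = p + wa * d + hs * e)
  }
  list(flex = mk(psi_f, phi_f, dhPf), ext = mk(psi_e, phi_e, dhPe),
       width = W * ws)
}

#' Pose a landmark exam realizing prescribed segment kinematics
#'
#' Builds vertebral corner landmarks, stacked caudal to cranial, such that
#' the measurement pipeline recovers each segment's prescribed rotation,
#' translation (%EPW) and per-phase anterior/posterior disc heights to
#' numerical precision.  Vertebrae are convex quadrilaterals whose exact
#' shape is irrelevant to the metrics; an optional random global similarity
#' (rotation, uniform scale, translation) is applied independently to each
#' radiograph to exercise the magnification invariance of the metrics.
#' Geometrically infeasible prescriptions (non-positive disc heights, or no
#' pose satisfying all constraints) raise an error naming the segment.
#'
#' @param truth Tibble with columns `level, rotation_deg,
#'   translation_pct_epw, adh_flex, adh_ext, pdh_flex, pdh_ext` for a
#'   contiguous run of level pairs (typically all five).
#' @param exam_id Identifier for the posed exam.
#' @param facing Patient orientation of the synthetic radiographs.
#' @param base_width Endplate width of the most caudal vertebra in
#'   arbitrary image units.
#' @param jitter Apply a random global similarity per radiograph.
#' @param condition,degeneration Passed through to [examLandmarks()].
#' @return An [examLandmarks()] object.
#' @export
poseLandmarks <- function(truth, exam_id = "posed", facing = "right",
                          base_width = 17, jitter = TRUE,
                          condition = NULL, degeneration = NULL) {
  pairs <- cervicalLevelPairs()
  truth <- truth[order(-match(truth$level, pairs)), , drop = FALSE]  # caudal first
  idx <- sort(match(truth$level, pairs))
  if (any(diff(idx) != 1L)) {
    stop("posed segments must form a contiguous run of level pairs")
  }
  # chain of vertebrae, most caudal first
  caudal <- sub(".*-", "", truth$level[1])
  h0 <- 0.7 * base_width
  base <- list(PS = c(0, 0), AS = c(base_width, 0),
               PI = c(0, -h0), AI = c(base_width, -h0))
  chain <- list(flex = stats::setNames(list(base), caudal),
                ext = stats::setNames(list(base), caudal))
  widths <- c(stats::setNames(base_width, caudal))
  for (r in seq_len(nrow(truth))) {
    seg <- truth[r, ]
    inf_l <- sub(".*-", "", seg$level)
    sup_l <- sub("-.*", "", seg$level)
    sol <- solveSegmentPose(widths[[inf_l]], seg$rotation_deg,
                            seg$translation_pct_epw,
                            seg$adh_flex, seg$adh_ext,
                            seg$pdh_flex, seg$pdh_ext,
                            label = seg$level)
    for (ph in c("flex", "ext")) {
      infv <- chain[[ph]][[inf_l]]
      u <- (infv$AS - infv$PS) / widths[[inf_l]]
      v <- c(-u[2], u[1])
      toGlobal <- function(p) infv$PS + p[1] * u + p[2] * v
      chain[[ph]][[sup_l]] <- lapply(sol[[ph]], toGlobal)
    }
    widths[[sup_l]] <- sol$width
  }
  buildRadiograph <- function(ph, phase_name) {
    sim <- if (jitter) {
      th <- stats::runif(1, -0.2, 0.2)
      s <- stats::runif(1, 0.8, 1.25)
      tr <- stats::runif(2, -40, 40)
      list(R = s * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2),
           t = tr)
    } else list(R = diag(2), t = c(0, 0))
    fx <- facingSign(facing)
    vv <- lapply(names(chain[[ph]]), function(lev) {
      corners <- do.call(rbind, chain[[ph]][[lev]][cornerRoles()])
      # anatomical (x anterior, y up) -> screen (x right, y down)
      scr <- cbind(fx * corners[, 1], -corners[, 2])
      scr <- t(sim$R %*% t(scr)) + rep(sim$t, each = nrow(scr))
      rownames(scr) <- cornerRoles()
      vertebraLandmarks(lev, scr)
    })
    radiographLandmarks(phase_name, vv, facing = facing)
  }
  examLandmarks(exam_id,
                buildRadiograph("flex", "flexion"),
                buildRadiograph("ext", "extension"),
                degeneration = degeneration, condition = condition)
}

#' Generate a landmark-level synthetic cohort
#'
#' Draws a metric cohort and poses each exam as corner landmarks, keeping
#' the ground truth alongside.  The metric model occasionally draws
#' combinations (far tails of translation relative to the disc heights)
#' that no rigid corner configuration can realize; such exams are redrawn
#' from the model until posable, which truncates a sub-percent tail of the
#' joint distribution.
#'
#' @inheritParams generateMetricCohort
#' @param jitter Apply random global similarities per radiograph (see
#'   [poseLandmarks()]).
#' @return List with `exams` (list of [examLandmarks()]) and `truth`
#'   (segment-level tibble matching the posed exams).
#' @export
generateLandmarkCohort <- function(cfg, n = 20, seed = NULL, jitter = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  truth_list <- vector("list", n)
  exams <- vector("list", n)
  ids <- character(n)
  for (i in seq_len(n)) {
    id <- sprintf("sim%05d", i)
    for (attempt in seq_len(25)) {
      rows <- drawExamRows(cfg, id)
      ex <- try(poseLandmarks(rows, exam_id = id, jitter = jitter),
                silent = TRUE)
      if (!inherits(ex, "try-error")) break
    }
    if (inherits(ex, "try-error")) {
      stop("could not pose exam ", id, " after 25 redraws; ",
           "generator configuration appears largely infeasible")
    }
    truth_list[[i]] <- rows
    exams[[i]] <- ex
    ids[i] <- id
  }
  names(exams) <- ids
  list(exams = exams, truth = do.call(rbind, truth_list))
}

#' Generate a synthetic sequential-sectioning experiment
#'
#' Emulates the cadaveric design: an intact arm drawn from the reference
#' model plus one arm per sectioning stage in which the target level
#' receives the configured cumulative shifts -- rotation increases, the
#' anterior/posterior disc openings exceed what the (shifted) rotation
#' predicts, and translation is generated from the pre-injury rotation so
#' it is essentially unchanged.  Zero shifts reduce every arm to the
#' reference model.
#'
#' @param cfg A [generatorConfig()] (its `injury` block defines stages,
#'   shifts and target level).
#' @param n_per_arm Specimens per arm (default 12).
#' @param seed Optional integer seed.
#' @return Segment-level tibble with a `condition` column (`"intact"` or a
#'   stage label) in the [examMetrics()] layout.
#' @export
generateSectioningExperiment <- function(cfg, n_per_arm = 12, seed = NULL) {
  stopifnot(inherits(cfg, "generator_config"), n_per_arm >= 1)
  if (!is.null(seed)) set.seed(seed)
  inj <- cfg$injury
  arms <- c("intact", inj$stages)
  out <- list()
  for (ai in seq_along(arms)) {
    arm <- arms[ai]
    injury <- if (arm == "intact") NULL else list(
      level = inj$target_level,
      rotation_shift = inj$rotation_shift[ai - 1],
      dadh_shift = inj$dadh_shift[ai - 1],
      dpdh_shift = inj$dpdh_shift[ai - 1],
      translation_shift = inj$translation_shift[ai - 1])
    for (i in seq_len(n_per_arm)) {
      rows <- drawExamRows(cfg, sprintf("%s_%02d", arm, i), injury)
      rows$condition <- arm
      out[[length(out) + 1L]] <- rows
    }
  }
  do.call(rbind, out)
}
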