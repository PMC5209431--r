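# Seeded synthetic cine generator: healthy and UVFP laryngeal kinematics
# with closed-form ground truth, so the whole pipeline is testable without
# imaging data.
#
# The glottis is idealised as a triangle with its apex at the anterior
# commissure: each fold's medial edge makes a task-dependent half-angle
# theta with the AC->PC axis, giving analytic hemi-areas
# 0.5 * L^2 * tan(theta) for an AP length L. Larynx elevation between
# sessions is modelled as a per-side additive angle offset (phonation far
# more sensitive than respiration, since the larynx elevates during
# phonation and the slice is fixed); this is the mechanism that degrades
# inter-session repeatability of phonation metrics.

#' Kinematic parameters for one simulated subject
#'
#' @param ap_length anterior-posterior glottal length, mm.
#' @param theta_resp,theta_phon abduction half-angles `c(left, right)` in
#'   degrees during respiration / phonation.
#' @param paralysis `"none"`, `"left"` or `"right"`; a paralysed fold
#'   holds `fixed_angle` in both tasks.
#' @param fixed_angle paramedian angle of the paralysed fold, degrees.
#' @param angle_jitter_sd per-frame within-task fluctuation SD, degrees.
#' @param elevation_shift_sd per-session larynx-elevation/slice-position
#'   shift SD, mm; converted to per-side angle offsets via
#'   `elevation_gain` (deg/mm, named `phonation` and `respiration`).
#' @param reader_noise_area,reader_noise_angle SD of reader-2 measurement
#'   noise, mm^2 and degrees.
#' @param frame_dt temporal resolution, s.
#' @param frames_per_period frames retained per 10-s task period.
#' @return a `kinematic_params` list.
#' @export
kinematic_params <- function(ap_length = 20,
                             theta_resp = c(25, 25),
                             theta_phon = c(1, 1),
                             paralysis = c("none", "left", "right"),
                             fixed_angle = 14,
                             angle_jitter_sd = 1.5,
                             elevation_shift_sd = 1,
                             elevation_gain = c(phonation = 1, respiration = 0.15),
                             reader_noise_area = 2,
                             reader_noise_angle = 1,
                             frame_dt = 0.764,
                             frames_per_period = 10) {
  paralysis <- match.arg(paralysis)
  stopifnot(ap_length > 0, frame_dt > 0, frames_per_period >= 1,
            all(theta_phon >= 0), all(theta_phon <= theta_resp),
            all(theta_resp <= 60), fixed_angle >= 0, fixed_angle <= 60)
  structure(list(ap_length = ap_length, theta_resp = theta_resp,
                 theta_phon = theta_phon, paralysis = paralysis,
                 fixed_angle = fixed_angle, angle_jitter_sd = angle_jitter_sd,
                 elevation_shift_sd = elevation_shift_sd,
                 elevation_gain = elevation_gain,
                 reader_noise_area = reader_noise_area,
                 reader_noise_angle = reader_noise_angle,
                 frame_dt = frame_dt, frames_per_period = frames_per_period),
            class = "kinematic_params")
}

# Task-dependent base half-angles c(left, right), paralysis applied.
base_angles <- function(params, task) {
  th <- if (task == "respiration") params$theta_resp else params$theta_phon
  if (params$paralysis == "left") th[1] <- params$fixed_angle
  if (params$paralysis == "right") th[2] <- params$fixed_angle
  th
}

#' Task schedule of a cine acquisition
#'
#' Alternating 10-s phonation/respiration blocks starting with phonation,
#' sampled every `frame_dt` seconds.
#'
#' @param total_s total scan duration, s (must cover at least one block of
#'   each task).
#' @param frame_dt temporal resolution, s.
#' @return data.frame with `frame` (1-based), `t` (s) and `task`.
#' @export
task_schedule <- function(total_s, frame_dt = 0.764) {
  if (frame_dt <= 0) stop("frame_dt must be positive")
  n <- floor(total_s / frame_dt + 1e-9) # complete acquisitions only
  if (n < 1) stop("scan too short: no complete frame")
  t <- (seq_len(n) - 1) * frame_dt
  block <- floor(t / 10)
  data.frame(frame = seq_along(t), t = t,
             task = ifelse(block %% 2 == 0, "phonation", "respiration"))
}

#' Idealised glottis polygon for one frame
#'
#' Triangle in mm coordinates local to the bisecting axis: apex at AC
#' (u = 0), posterior base at the PC level (u = L); the medial edge of
#' each fold makes its (jittered) half-angle with the axis. `v > 0` is the
#' subject-left side.
#'
#' @param params a [kinematic_params()].
#' @param task `"phonation"` or `"respiration"`.
#' @param jitter per-frame angle deviations `c(left, right)`, degrees.
#' @param elevation_offset per-side angle offsets from the session
#'   elevation shift, degrees.
#' @return list with `vertices` (u, v in mm), `angles` (deg, c(left,
#'   right)), `ap_length`, and analytic `left_area`, `right_area` (mm^2).
#' @export
glottis_polygon <- function(params, task, jitter = c(0, 0),
                            elevation_offset = c(0, 0)) {
  th <- pmin(pmax(base_angles(params, task) + jitter + elevation_offset, 0), 89)
  L <- params$ap_length
  rad <- th * pi / 180
  verts <- rbind(c(0, 0), c(L, L * tan(rad[1])), c(L, -L * tan(rad[2])))
  colnames(verts) <- c("u", "v")
  list(vertices = verts, angles = th, ap_length = L,
       left_area = 0.5 * L^2 * tan(rad[1]),
       right_area = 0.5 * L^2 * tan(rad[2]))
}

#' Rasterize a glottis polygon into a cine frame
#'
#' Places the polygon in a field of view (default 240 x 180 mm, matching a
#' 160 x 120 grid at 1.5 mm) with AC at pixel `ac_px` and the AC->PC axis
#' pointing down the image (+y); subject-left (v > 0) maps to image-right
#' (radiological display). The default AC column (79.5) puts the
#' bisecting axis midway between pixel columns so that no pixel center
#' lies exactly on a polygon edge shared between tasks: an immobile
#' fold's rasterized hemi-area is then identical across tasks. Mask mode
#' rasterizes at pixel centers; intensity mode renders a two-level image
#' (airway dark) plus seeded Gaussian noise.
#'
#' @param poly output of [glottis_polygon()].
#' @param spacing mm per pixel `c(sx, sy)`.
#' @param mode `"mask"` or `"intensity"`.
#' @param noise_sd Gaussian noise SD (intensity units) for intensity mode.
#' @param seed integer seed for the noise draw.
#' @param fov field of view in mm `c(x, y)`.
#' @param ac_px AC position in pixel coordinates (0-based).
#' @param task,t metadata stored on the frame.
#' @param tissue,airway the two intensity levels.
#' @return a [glottal_frame()].
#' @export
render_frame <- function(poly, spacing = c(1.5, 1.5),
                         mode = c("mask", "intensity"),
                         noise_sd = 0, seed = 1, fov = c(240, 180),
                         ac_px = c(79.5, 24), task = "respiration", t = NA_real_,
                         tissue = 0.8, airway = 0.2) {
  mode <- match.arg(mode)
  nc <- round(fov[1] / spacing[1]); nr <- round(fov[2] / spacing[2])
  ac_mm <- ac_px * spacing
  # local (u, v) -> image mm: +u down the image, +v to image-right
  px <- ac_mm[1] + poly$vertices[, "v"]
  py <- ac_mm[2] + poly$vertices[, "u"]
  if (any(px < 0 | px > (nc - 1) * spacing[1] | py < 0 | py > (nr - 1) * spacing[2]))
    stop("polygon exceeds the field of view")

  mask <- matrix(0, nr, nc)
  if (poly$left_area + poly$right_area > 1e-9) {
    jr <- range(px); ir <- range(py)
    cols <- max(1, floor(jr[1] / spacing[1])):min(nc, ceiling(jr[2] / spacing[1]) + 1)
    rows <- max(1, floor(ir[1] / spacing[2])):min(nr, ceiling(ir[2] / spacing[2]) + 1)
    cx <- (cols - 1) * spacing[1]
    cy <- (rows - 1) * spacing[2]
    inside <- pracma::inpolygon(rep(cx, each = length(cy)),
                                rep(cy, times = length(cx)),
                                px, py, boundary = FALSE)
    mask[rows, cols] <- matrix(as.numeric(inside), length(rows), length(cols))
  }
  lms <- landmark_set(ac_px, ac_px + c(0, poly$ap_length / spacing[2]))
  if (mode == "mask")
    return(glottal_frame(mask, spacing, task, t, lms))
  img <- matrix(tissue, nr, nc)
  img[mask == 1] <- airway
  if (noise_sd > 0)
    img <- img + with_seed(seed, matrix(rnorm(nr * nc, 0, noise_sd), nr, nc))
  glottal_frame(img, spacing, task, t, lms)
}

#' Simulate one subject's cine studies
#'
#' Generates the study design of the emulated protocol: studies 1 and 2 in
#' one scan session (sharing the session's larynx-elevation offset),
#' study 3 in a second session with a fresh offset; 10 phonation + 10
#' respiration frames per study. Reader 1's measurements are the pipeline
#' measurement (rendered modes) or the analytic ground truth (`"analytic"`
#' mode); reader 2's are reader 1's plus seeded reader noise.
#'
#' @param params a [kinematic_params()].
#' @param subject subject id string.
#' @param cohort cohort label stored with the rows.
#' @param studies which of studies 1:3 to simulate.
#' @param readers reader ids (reader 1 must be included).
#' @param master_seed integer; all randomness derives from it.
#' @param mode `"analytic"` (closed-form measurements, no rendering),
#'   `"mask"` or `"intensity"`.
#' @param spacing mm per pixel for rendered modes.
#' @param noise_sd intensity-noise SD for `"intensity"` mode.
#' @return list with `measurements` and `ground_truth` data.frames and,
#'   for rendered modes, `frames` (nested list by study).
#' @export
simulate_subject <- function(params, subject = "S1", cohort = "healthy",
                             studies = 1:3, readers = 1:2, master_seed = 1,
                             mode = c("analytic", "mask", "intensity"),
                             spacing = c(1.5, 1.5), noise_sd = 0) {
  mode <- match.arg(mode)
  stopifnot(1 %in% readers)
  n <- params$frames_per_period
  nf <- 2L * n
  task <- rep(c("phonation", "respiration"), each = n)
  tt <- c((0:(n - 1)) * params$frame_dt, 10 + (0:(n - 1)) * params$frame_dt)
  L <- params$ap_length

  meas <- list(); truth <- list(); frames <- list()
  for (study in studies) {
    session <- if (study <= 2) 1L else 2L
    elev <- with_seed(derive_seed(master_seed, subject, "session", session),
                      rnorm(2, 0, params$elevation_shift_sd))
    jit <- with_seed(derive_seed(master_seed, subject, study, "jitter"),
                     matrix(rnorm(2 * nf, 0, params$angle_jitter_sd), nf, 2))
    gain <- params$elevation_gain[ifelse(task == "phonation",
                                         "phonation", "respiration")]
    base <- t(vapply(task, function(tk) base_angles(params, tk), c(0, 0)))
    th <- pmin(pmax(base + jit + outer(unname(gain), elev), 0), 89)
    areas <- 0.5 * L^2 * tan(th * pi / 180)

    truth[[length(truth) + 1]] <- data.frame(
      subject = subject, study = study, task = task, frame = seq_len(nf),
      t = tt, left_area = areas[, 1], right_area = areas[, 2],
      left_angle = th[, 1], right_angle = th[, 2])

    if (mode == "analytic") {
      m1 <- data.frame(left_area = areas[, 1], right_area = areas[, 2],
                       left_angle = th[, 1], right_angle = th[, 2],
                       valid_left_area = TRUE, valid_right_area = TRUE,
                       valid_left_angle = th[, 1] > 1e-9,
                       valid_right_angle = th[, 2] > 1e-9)
    } else {
      study_frames <- vector("list", nf)
      mrows <- vector("list", nf)
      for (i in seq_len(nf)) {
        poly <- glottis_polygon(params, task[i], jitter = jit[i, ],
                                elevation_offset = gain[i] * elev)
        fr <- render_frame(poly, spacing = spacing, mode = mode,
                           noise_sd = noise_sd,
                           seed = derive_seed(master_seed, subject, study, "noise", i),
                           task = task[i], t = tt[i])
        study_frames[[i]] <- fr
        m <- measure_frame(fr)
        mrows[[i]] <- data.frame(
          left_area = m$left_area, right_area = m$right_area,
          left_angle = m$left_angle, right_angle = m$right_angle,
          valid_left_area = unname(m$valid["left_area"]),
          valid_right_area = unname(m$valid["right_area"]),
          valid_left_angle = unname(m$valid["left_angle"]),
          valid_right_angle = unname(m$valid["right_angle"]))
      }
      frames[[as.character(study)]] <- study_frames
      m1 <- do.call(rbind, mrows)
    }

    for (reader in readers) {
      m <- m1
      if (reader != 1) {
        rn <- with_seed(derive_seed(master_seed, subject, study, "reader", reader),
                        matrix(rnorm(4 * nf), nf, 4))
        m$left_area <- pmax(0, m$left_area + rn[, 1] * params$reader_noise_area)
        m$right_area <- pmax(0, m$right_area + rn[, 2] * params$reader_noise_area)
        m$left_angle <- pmin(90, pmax(0, m$left_angle + rn[, 3] * params$reader_noise_angle))
        m$right_angle <- pmin(90, pmax(0, m$right_angle + rn[, 4] * params$reader_noise_angle))
      }
      meas[[length(meas) + 1]] <- cbind(
        data.frame(subject = subject, cohort = cohort, study = study,
                   reader = reader, task = task, frame = seq_len(nf), t = tt),
        m)
    }
  }
  out <- list(measurements = do.call(rbind, c(meas, list(make.row.names = FALSE))),
              ground_truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
  if (mode != "analytic") out$frames <- frames
  out
}

#' Cohort configuration for [simulate_cohort()]
#'
#' Defaults emulate the study design: 5 healthy subjects and 9 UVFP
#' (left-paralysis) patients; all subjects get studies 1-2, all healthy
#' and 5 of the 9 patients get the inter-session study 3; two readers on
#' study 1 only. Per-subject angles are drawn from truncated normal
#' distributions (clamped to the stated ranges).
#'
#' @param n_healthy,n_uvfp cohort sizes.
#' @param n_uvfp_study3 patients receiving the inter-session study.
#' @param healthy_resp,healthy_phon mean and SD (deg) of healthy
#'   half-angles (both folds; symmetric unless
#'   `independent_sides = TRUE`).
#' @param uvfp_fixed mean and SD (deg) of the paralysed fold's paramedian
#'   angle.
#' @param uvfp_healthy_phon mean and SD (deg) of the patient healthy-side
#'   phonation half-angle (incomplete compensation leaves it above the
#'   healthy residual).
#' @param independent_sides draw left and right respiration angles
#'   independently for every subject (used for parameter-recovery
#'   experiments); paralysis is then disabled.
#' @param mode,spacing,noise_sd passed to [simulate_subject()].
#' @param ... overrides forwarded to [kinematic_params()] (e.g.
#'   `angle_jitter_sd`, `elevation_shift_sd`, `reader_noise_area`).
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_healthy = 5, n_uvfp = 9, n_uvfp_study3 = 5,
                          healthy_resp = c(25, 4), healthy_phon = c(1, 0),
                          uvfp_fixed = c(14, 3), uvfp_healthy_phon = c(5, 2),
                          independent_sides = FALSE,
                          mode = "analytic", spacing = c(1.5, 1.5),
                          noise_sd = 0, ...) {
  structure(list(n_healthy = n_healthy, n_uvfp = n_uvfp,
                 n_uvfp_study3 = n_uvfp_study3, healthy_resp = healthy_resp,
                 healthy_phon = healthy_phon, uvfp_fixed = uvfp_fixed,
                 uvfp_healthy_phon = uvfp_healthy_phon,
                 independent_sides = independent_sides, mode = mode,
                 spacing = spacing, noise_sd = noise_sd,
                 param_overrides = list(...)),
            class = "cohort_config")
}

rnorm_clamped <- function(n, mean_sd, lo, hi)
  pmin(pmax(rnorm(n, mean_sd[1], mean_sd[2]), lo), hi)

#' Simulate a full cohort
#'
#' @param config a [cohort_config()].
#' @param master_seed integer master seed; the dataset is bit-reproducible
#'   from it.
#' @return list with `measurements`, `ground_truth`, `subjects` (id,
#'   cohort, study-3 flag, generating parameters), `config`, `master_seed`.
#' @export
simulate_cohort <- function(config = cohort_config(), master_seed = 1) {
  subj <- list(); meas <- list(); truth <- list()
  build_params <- function(...)
    do.call(kinematic_params, c(list(...), config$param_overrides))

  ids <- c(sprintf("H%02d", seq_len(config$n_healthy)),
           sprintf("P%02d", seq_len(config$n_uvfp)))
  cohorts <- rep(c("healthy", "uvfp"), c(config$n_healthy, config$n_uvfp))

  for (idx in seq_along(ids)) {
    id <- ids[idx]; cohort <- cohorts[idx]
    draws <- with_seed(derive_seed(master_seed, id, "params"), rnorm(6))
    clamp <- function(z, ms, lo, hi) pmin(pmax(ms[1] + z * ms[2], lo), hi)
    if (config$independent_sides) {
      th_resp <- clamp(draws[1:2], config$healthy_resp, 8, 45)
      th_phon <- min(clamp(draws[3], config$healthy_phon, 0.5, 15),
                     min(th_resp) - 0.5)
      params <- build_params(theta_resp = th_resp,
                             theta_phon = rep(th_phon, 2), paralysis = "none")
    } else if (cohort == "healthy") {
      th <- clamp(draws[1], config$healthy_resp, 10, 45)
      ph <- min(clamp(draws[3], config$healthy_phon, 0.5, 10), th - 0.5)
      params <- build_params(theta_resp = c(th, th), theta_phon = c(ph, ph),
                             paralysis = "none")
    } else {
      th <- clamp(draws[1], config$healthy_resp, 10, 45)
      fx <- clamp(draws[2], config$uvfp_fixed, 5, 30)
      ph <- min(clamp(draws[3], config$uvfp_healthy_phon, 1, 15), th - 0.5)
      params <- build_params(theta_resp = c(fx, th), theta_phon = c(fx, ph),
                             paralysis = "left", fixed_angle = fx)
    }
    has3 <- cohort == "healthy" ||
      match(id, ids[cohorts == "uvfp"]) <= config$n_uvfp_study3
    studies <- if (has3) 1:3 else 1:2
    sim <- simulate_subject(params, subject = id, cohort = cohort,
                            studies = studies, readers = 1:2,
                            master_seed = derive_seed(master_seed, id),
                            mode = config$mode, spacing = config$spacing,
                            noise_sd = config$noise_sd)
    # reader 2 read study 1 only in the emulated design
    sim$measurements <- sim$measurements[
      sim$measurements$reader == 1 | sim$measurements$study == 1, ]
    meas[[id]] <- sim$measurements
    truth[[id]] <- sim$ground_truth
    subj[[id]] <- data.frame(subject = id, cohort = cohort, has_study3 = has3,
                             theta_resp_L = params$theta_resp[1],
                             theta_resp_R = params$theta_resp[2],
                             theta_phon_L = base_angles(params, "phonation")[1],
                             theta_phon_R = base_angles(params, "phonation")[2],
                             paralysis = params$paralysis)
  }
  list(measurements = do.call(rbind, c(meas, list(make.row.names = FALSE))),
       ground_truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
       subjects = do.call(rbind, c(subj, list(make.row.names = FALSE))),
       config = config, master_seed = master_seed)
}
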