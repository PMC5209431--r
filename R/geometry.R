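# Frame-level geometry: bisecting line, hemi-areas, hemi-angles.
#
# Coordinate convention (used everywhere): 0-based pixel-center coordinates,
# x = column, y = row; a pixel at R index [i, j] has pixel coordinates
# (j - 1, i - 1) and physical coordinates ((j - 1) * sx, (i - 1) * sy) mm.

#' Anterior/posterior commissure landmark pair
#'
#' @param ac,pc numeric length-2 points (x = column, y = row), 0-based
#'   pixel-center coordinates; fractional positions are allowed.
#' @return a `landmark_set` list.
#' @export
landmark_set <- function(ac, pc) {
  ac <- as.numeric(ac); pc <- as.numeric(pc)
  stopifnot(length(ac) == 2, length(pc) == 2, all(is.finite(c(ac, pc))))
  structure(list(ac = ac, pc = pc), class = "landmark_set")
}

#' One axial cine frame
#'
#' Holds either an intensity image or a binary airway mask, with pixel
#' spacing, task label, acquisition time and AC/PC landmarks.
#'
#' @param image numeric matrix (rows = y, columns = x); binary masks hold
#'   values in \{0, 1\}.
#' @param spacing mm per pixel, `c(sx, sy)`; default 1.5 x 1.5 mm.
#' @param task `"phonation"` or `"respiration"`.
#' @param t seconds from series start.
#' @param landmarks a [landmark_set()].
#' @return a `glottal_frame` list.
#' @export
glottal_frame <- function(image, spacing = c(1.5, 1.5),
                          task = c("phonation", "respiration"),
                          t = NA_real_, landmarks) {
  stopifnot(is.matrix(image), all(spacing > 0), length(spacing) == 2)
  task <- match.arg(task)
  stopifnot(inherits(landmarks, "landmark_set"))
  lm <- c(landmarks$ac, landmarks$pc)
  if (any(lm[c(1, 3)] < 0) || any(lm[c(1, 3)] > ncol(image) - 1) ||
      any(lm[c(2, 4)] < 0) || any(lm[c(2, 4)] > nrow(image) - 1))
    stop("landmarks lie outside the frame bounds")
  structure(list(image = image, spacing = as.numeric(spacing), task = task,
                 t = t, landmarks = landmarks),
            class = "glottal_frame")
}

is_binary_image <- function(image) {
  u <- unique(as.vector(image))
  length(u) <= 2 && all(u %in% c(0, 1))
}

#' Commissure-bisecting line
#'
#' Oriented line through the anterior and posterior commissures, direction
#' normalised AC -> PC, together with a signed-distance function in mm.
#' By default positive signed distance is the subject-left side, mapping
#' image-right to subject-left (radiological display); set
#' `left_positive = FALSE` to flip the convention.
#'
#' @param landmarks a [landmark_set()].
#' @param spacing mm per pixel `c(sx, sy)`.
#' @param left_positive logical; see above.
#' @return list with `point` (AC, mm), `dir` (unit AC->PC), `length` (mm)
#'   and `signed_distance(x_mm, y_mm)`.
#' @export
bisecting_line <- function(landmarks, spacing = c(1, 1), left_positive = TRUE) {
  ac <- landmarks$ac * spacing
  pc <- landmarks$pc * spacing
  v <- pc - ac
  len <- sqrt(sum(v^2))
  if (len < 1e-9 * max(spacing))
    stop("degenerate geometry: anterior and posterior commissures coincide")
  d <- v / len
  sgn <- if (left_positive) 1 else -1
  structure(list(
    point = ac, dir = d, length = len,
    signed_distance = function(x, y) sgn * (d[2] * (x - ac[1]) - d[1] * (y - ac[2])),
    axial_coordinate = function(x, y) d[1] * (x - ac[1]) + d[2] * (y - ac[2])
  ), class = "bisecting_line")
}

# Physical (mm) coordinates of foreground pixel centers of a binary mask.
mask_coords_mm <- function(mask, spacing) {
  ij <- which(mask > 0, arr.ind = TRUE)
  cbind(x = (ij[, 2] - 1) * spacing[1], y = (ij[, 1] - 1) * spacing[2])
}

#' Left/right hemi-glottal areas
#'
#' Assigns every airway pixel to the left or right side by the sign of the
#' signed distance of its center to the commissure-bisecting line; pixels
#' whose centers fall exactly on the line contribute half their area to
#' each side, so `left + right` equals the total mask area exactly.
#'
#' @param mask binary matrix.
#' @inheritParams bisecting_line
#' @return list with `left_area`, `right_area` (mm^2) and `valid`.
#' @export
hemi_areas <- function(mask, landmarks, spacing = c(1.5, 1.5),
                       left_positive = TRUE) {
  pa <- spacing[1] * spacing[2]
  xy <- mask_coords_mm(mask, spacing)
  if (nrow(xy) == 0)
    return(list(left_area = 0, right_area = 0, valid = FALSE))
  line <- bisecting_line(landmarks, spacing, left_positive)
  s <- line$signed_distance(xy[, 1], xy[, 2])
  tol <- 1e-7 * max(spacing)
  n_left <- sum(s > tol)
  n_right <- sum(s < -tol)
  n_tie <- length(s) - n_left - n_right
  list(left_area = (n_left + n_tie / 2) * pa,
       right_area = (n_right + n_tie / 2) * pa,
       valid = TRUE)
}

#' Left/right hemi-glottal angles
#'
#' For each side, the medial fold edge is taken as the laterally outermost
#' airway pixel per axial position along the AC->PC axis; a least-squares
#' line constrained through the anterior commissure is fitted to those edge
#' points and the acute angle (degrees) between the fit and the bisecting
#' line is returned. Edge-pixel centers sit up to one lateral pixel inside
#' the true fold edge, so half the lateral pixel quantum is added to each
#' edge distance (the expected offset), removing the systematic
#' underestimate of the angle at coarse spacing.
#'
#' @inheritParams hemi_areas
#' @return list with `left_angle`, `right_angle` (degrees) and
#'   `valid = c(left, right)`.
#' @export
hemi_angles <- function(mask, landmarks, spacing = c(1.5, 1.5),
                        left_positive = TRUE) {
  xy <- mask_coords_mm(mask, spacing)
  out <- list(left_angle = NA_real_, right_angle = NA_real_,
              valid = c(left = FALSE, right = FALSE))
  if (nrow(xy) == 0) return(out)
  line <- bisecting_line(landmarks, spacing, left_positive)
  s <- line$signed_distance(xy[, 1], xy[, 2])
  u <- line$axial_coordinate(xy[, 1], xy[, 2])
  tol <- 1e-7 * max(spacing)
  bw <- min(spacing)
  # lateral distance quantum: |s| change when stepping one pixel sideways
  d <- line$dir
  quant <- abs(d[2]) * spacing[1] + abs(d[1]) * spacing[2]

  fit_side <- function(keep, any_tie) {
    if (!any(keep)) {
      # mask collapsed onto the line: the fold edge is collinear with it
      if (any_tie) return(c(angle = 0, valid = 1))
      return(c(angle = NA_real_, valid = 0))
    }
    us <- u[keep]; ws <- abs(s[keep])
    pos <- us > 0.25 * bw  # edge points anterior of AC carry no angle signal
    if (!any(pos)) return(c(angle = NA_real_, valid = 0))
    us <- us[pos]; ws <- ws[pos]
    bins <- round(us / bw)
    edge <- vapply(split(seq_along(us), bins), function(i) i[which.max(ws[i])], 1L)
    uu <- us[edge]; ww <- ws[edge] + quant / 2
    tanth <- sum(uu * ww) / sum(uu^2)
    c(angle = atan(tanth) * 180 / pi, valid = 1)
  }

  any_tie <- any(abs(s) <= tol)
  L <- fit_side(s > tol, any_tie)
  R <- fit_side(s < -tol, any_tie)
  list(left_angle = unname(L["angle"]), right_angle = unname(R["angle"]),
       valid = c(left = unname(L["valid"]) == 1, right = unname(R["valid"]) == 1))
}

#' Segment the glottal airway from an intensity frame
#'
#' Automated stand-in for the manual regions of interest: a global Otsu
#' threshold (airway polarity per `polarity`) followed by 4-connected
#' region growth from a seed on the AC->PC axis, restricted to a
#' neighbourhood of the commissures. Binary input passes through
#' unchanged.
#'
#' @param frame a [glottal_frame()].
#' @param seed_offset fraction along AC->PC at which the seed is placed.
#' @param polarity `"dark"` if the airway is darker than tissue.
#' @param window half-width of the allowed neighbourhood, as a fraction of
#'   the AC-PC distance.
#' @return binary matrix (the airway mask).
#' @export
segment_airway <- function(frame, seed_offset = 0.5,
                           polarity = c("dark", "bright"), window = 0.75) {
  polarity <- match.arg(polarity)
  img <- frame$image
  if (is_binary_image(img)) return(img)

  rng <- range(img)
  thr <- EBImage::otsu(img, range = rng)
  cand <- if (polarity == "dark") img < thr else img > thr

  ac <- frame$landmarks$ac; pc <- frame$landmarks$pc
  seed <- round(ac + seed_offset * (pc - ac)) # pixel coords, 0-based
  nr <- nrow(img); nc <- ncol(img)
  si <- seed[2] + 1; sj <- seed[1] + 1
  if (si < 1 || si > nr || sj < 1 || sj > nc)
    stop("segmentation seed falls outside the frame")
  if (!cand[si, sj])
    stop("empty segmentation: seed pixel is not airway-like at the Otsu threshold")

  # confine growth near the commissures so leaks cannot cross the frame
  half <- window * sqrt(sum((pc - ac)^2))
  jr <- range(ac[1], pc[1]) + c(-half, half)
  ir <- range(ac[2], pc[2]) + c(-half, half)
  allowed <- matrix(FALSE, nr, nc)
  allowed[max(1, floor(ir[1]) + 1):min(nr, ceiling(ir[2]) + 1),
          max(1, floor(jr[1]) + 1):min(nc, ceiling(jr[2]) + 1)] <- TRUE
  cand <- cand & allowed

  flood_fill4(cand, si, sj)
}

# 4-connected flood fill from (si, sj) within `cand`; returns 0/1 matrix.
flood_fill4 <- function(cand, si, sj) {
  nr <- nrow(cand); nc <- ncol(cand)
  visited <- matrix(FALSE, nr, nc)
  queue <- integer(sum(cand))
  start <- (sj - 1L) * nr + si
  queue[1] <- start
  visited[start] <- TRUE
  head <- 1L; tail <- 1L
  while (head <= tail) {
    p <- queue[head]; head <- head + 1L
    i <- ((p - 1L) %% nr) + 1L
    j <- ((p - 1L) %/% nr) + 1L
    for (q in c(if (i > 1L) p - 1L, if (i < nr) p + 1L,
                if (j > 1L) p - nr, if (j < nc) p + nr)) {
      if (cand[q] && !visited[q]) {
        visited[q] <- TRUE
        tail <- tail + 1L
        queue[tail] <- q
      }
    }
  }
  mask <- matrix(0, nr, nc)
  mask[visited] <- 1
  mask
}

#' Measurement policy for [measure_frame()]
#'
#' @param left_positive laterality convention, see [bisecting_line()].
#' @param polarity airway polarity for intensity input.
#' @param seed_offset seed position for segmentation.
#' @export
measure_policy <- function(left_positive = TRUE, polarity = "dark",
                           seed_offset = 0.5) {
  list(left_positive = left_positive, polarity = polarity,
       seed_offset = seed_offset)
}

#' Measure one frame
#'
#' Composes segmentation (for intensity input), [hemi_areas()] and
#' [hemi_angles()]. Failures propagate as per-quantity validity flags
#' rather than errors. An empty *binary* mask is a true observation of a
#' fully adducted glottis: areas are valid zeros (angles stay invalid). A
#' failed segmentation of an intensity frame invalidates everything.
#'
#' @param frame a [glottal_frame()].
#' @param policy a [measure_policy()].
#' @return a `hemi_measurement` list: `left_area`, `right_area` (mm^2),
#'   `left_angle`, `right_angle` (deg) and a named logical `valid`.
#' @export
measure_frame <- function(frame, policy = measure_policy()) {
  invalid <- structure(list(
    left_area = NA_real_, right_area = NA_real_,
    left_angle = NA_real_, right_angle = NA_real_,
    valid = c(left_area = FALSE, right_area = FALSE,
              left_angle = FALSE, right_angle = FALSE)),
    class = "hemi_measurement")

  binary_in <- is_binary_image(frame$image)
  mask <- tryCatch(
    segment_airway(frame, seed_offset = policy$seed_offset,
                   polarity = policy$polarity),
    error = function(e) NULL)
  if (is.null(mask)) return(invalid)

  a <- hemi_areas(mask, frame$landmarks, frame$spacing, policy$left_positive)
  g <- hemi_angles(mask, frame$landmarks, frame$spacing, policy$left_positive)
  area_ok <- a$valid || binary_in # empty binary mask = closed glottis, area 0
  structure(list(
    left_area = if (area_ok) a$left_area else NA_real_,
    right_area = if (area_ok) a$right_area else NA_real_,
    left_angle = g$left_angle, right_angle = g$right_angle,
    valid = c(left_area = area_ok, right_area = area_ok,
              left_angle = unname(g$valid["left"]),
              right_angle = unname(g$valid["right"]))),
    class = "hemi_measurement")
}

#' Aggregate frame measurements over one task period
#'
#' Arithmetic mean per quantity over the frames where that quantity is
#' valid; the total area is the sum of the two mean hemi-areas.
#'
#' @param measurements list of `hemi_measurement` objects (one task period).
#' @return a `period_summary` list.
#' @export
period_summary <- function(measurements) {
  stopifnot(length(measurements) >= 1)
  get <- function(field) vapply(measurements, function(m) as.numeric(m[[field]]), 1)
  okq <- function(field) vapply(measurements, function(m) isTRUE(m$valid[[field]]), TRUE)

  a_ok <- okq("left_area") & okq("right_area")
  if (!any(a_ok)) stop("empty period: no frame with valid hemi-areas")
  mean_valid <- function(x, ok) if (any(ok)) mean(x[ok]) else NA_real_

  la <- mean(get("left_area")[a_ok])
  ra <- mean(get("right_area")[a_ok])
  structure(list(
    mean_left_area = la, mean_right_area = ra,
    mean_left_angle = mean_valid(get("left_angle"), okq("left_angle")),
    mean_right_angle = mean_valid(get("right_angle"), okq("right_angle")),
    total_area = la + ra,
    n_frames = sum(a_ok)), class = "period_summary")
}

#' @export
print.period_summary <- function(x, ...) {
  cat(sprintf("Period summary over %d frames\n", x$n_frames))
  cat(sprintf("  hemi-areas  L %.2f / R %.2f mm^2 (total %.2f)\n",
              x$mean_left_area, x$mean_right_area, x$total_area))
  cat(sprintf("  hemi-angles L %.1f / R %.1f deg\n",
              x$mean_left_angle, x$mean_right_angle))
  invisible(x)
}
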