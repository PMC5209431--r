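# Frame geometry: bisecting line, hemi-areas, hemi-angles, segmentation,
# per-period aggregation.

test_that("bisecting line passes through the landmarks, oriented AC->PC", {
  bl <- bisecting_line(landmark_set(c(5, 0), c(5, 10)))
  expect_equal(bl$dir, c(0, 1))
  expect_equal(bl$signed_distance(5, 7), 0)
  # image-right of a downward axis is positive (subject-left, radiological)
  expect_gt(bl$signed_distance(8, 3), 0)
  expect_lt(bisecting_line(landmark_set(c(5, 0), c(5, 10)),
                           left_positive = FALSE)$signed_distance(8, 3), 0)

  diag45 <- bisecting_line(landmark_set(c(0, 0), c(10, 10)))
  expect_equal(diag45$dir, c(1, 1) / sqrt(2))
  expect_equal(diag45$signed_distance(5, 5), 0)

  expect_error(bisecting_line(landmark_set(c(3, 3), c(3, 3))), "degenerate")
})

test_that("hemi-areas match manual pixel enumeration and unit scaling", {
  # axis x = 3 pointing up the image (PC above AC): pixels at x in {1,2}
  # land subject-left, the two at x = 4 subject-right
  px <- rbind(cbind(1, 2:3), cbind(2, 2:3), cbind(4, c(2, 5)))
  mask <- mask_from_pixels(px)
  lm <- landmark_set(c(3, 9), c(3, 0))
  a <- hemi_areas(mask, lm, spacing = c(1, 1))
  expect_equal(a$left_area, 4.0)
  expect_equal(a$right_area, 2.0)
  expect_true(a$valid)

  a15 <- hemi_areas(mask, lm, spacing = c(1.5, 1.5))
  expect_equal(a15$left_area, 4.0 * 2.25)
  expect_equal(a15$right_area, 2.0 * 2.25)
})

test_that("pixels exactly on the line split half-half, conserving area", {
  # 3-wide column straddling the axis x = 5
  px <- as.matrix(expand.grid(4:6, 2:8)); colnames(px) <- NULL
  mask <- mask_from_pixels(px)
  a <- hemi_areas(mask, landmark_set(c(5, 0), c(5, 11)), spacing = c(1, 1))
  expect_equal(a$left_area, a$right_area)
  expect_equal(a$left_area + a$right_area, sum(mask))
})

test_that("area conservation and mirror covariance hold on random masks", {
  set.seed(41)
  for (i in 1:50) {
    mask <- random_blob_mask(40, 40)
    # random oblique line for conservation
    lm <- landmark_set(runif(2, 5, 34), runif(2, 5, 34))
    sp <- c(1.5, 1.5)
    a <- hemi_areas(mask, lm, sp)
    if (!a$valid) next
    expect_equal(a$left_area + a$right_area, sum(mask) * sp[1] * sp[2],
                 tolerance = 1e-12)
    # mirror about a vertical axis through the grid center
    lmv <- landmark_set(c(19.5, 2), c(19.5, 38))
    av <- hemi_areas(mask, lmv, sp)
    gv <- hemi_angles(mask, lmv, sp)
    flipped <- mask[, ncol(mask):1]
    af <- hemi_areas(flipped, lmv, sp)
    gf <- hemi_angles(flipped, lmv, sp)
    expect_equal(af$left_area, av$right_area)
    expect_equal(af$right_area, av$left_area)
    expect_equal(gf$left_angle, gv$right_angle)
    expect_equal(gf$right_angle, gv$left_angle)
  }
})

test_that("hemi-angles recover constructed fold half-angles", {
  fr <- triangle_frame(c(20, 20))
  g <- hemi_angles(fr$image, fr$landmarks, fr$spacing)
  expect_equal(g$left_angle, 20, tolerance = 1.5 / 20)
  expect_equal(g$right_angle, 20, tolerance = 1.5 / 20)
  expect_true(all(g$valid))

  # asymmetric paralysis posture: a 2-degree fold is sub-pixel at 1.5 mm,
  # so recovery is checked at finer spacing
  fr2 <- triangle_frame(c(2, 30), sp = 0.375)
  g2 <- hemi_angles(fr2$image, fr2$landmarks, fr2$spacing)
  expect_equal(g2$left_angle, 2, tolerance = 1.5 / 2)
  expect_equal(g2$right_angle, 30, tolerance = 1.5 / 30)
})

test_that("a mask collapsed onto the bisecting line has zero fold angle", {
  px <- cbind(5, 3:8)
  mask <- mask_from_pixels(px)
  g <- hemi_angles(mask, landmark_set(c(5, 2), c(5, 9)), spacing = c(1, 1))
  expect_equal(g$left_angle, 0)
  expect_equal(g$right_angle, 0)
})

test_that("empty or one-sided masks flag the affected quantities", {
  empty <- matrix(0, 8, 8)
  lm <- landmark_set(c(4, 1), c(4, 6))
  expect_false(hemi_areas(empty, lm)$valid)
  expect_false(any(hemi_angles(empty, lm)$valid))

  right_only <- mask_from_pixels(cbind(c(1, 2), c(3, 4)))
  g <- hemi_angles(right_only, landmark_set(c(4, 0), c(4, 7)), c(1, 1))
  expect_false(g$valid[["left"]])
  expect_true(g$valid[["right"]])
  expect_true(is.na(g$left_angle))
})

test_that("segmentation reproduces the rasterized polygon and rejects bad seeds", {
  p <- kinematic_params(theta_resp = c(22, 26), angle_jitter_sd = 0)
  poly <- glottis_polygon(p, "respiration")
  truth <- render_frame(poly, mode = "mask")$image
  clean <- render_frame(poly, mode = "intensity", noise_sd = 0)
  expect_identical(segment_airway(clean), truth)

  # SNR 20 on the 0.6 tissue-airway contrast
  noisy <- render_frame(poly, mode = "intensity", noise_sd = 0.6 / 20, seed = 7)
  seg <- segment_airway(noisy)
  dice <- 2 * sum(seg * truth) / (sum(seg) + sum(truth))
  expect_gte(dice, 0.95)

  # binary input passes through untouched
  fr <- render_frame(poly, mode = "mask")
  expect_identical(segment_airway(fr), fr$image)

  # seed far outside the airway: landmarks placed in uniform tissue
  bad <- clean
  bad$landmarks <- landmark_set(c(10, 10), c(10, 30))
  expect_error(segment_airway(bad), "empty segmentation|seed")
})

test_that("measure_frame composes the steps and flags failures per quantity", {
  fr <- triangle_frame(c(18, 18))
  m <- measure_frame(fr)
  expect_equal(m$left_area, m$right_area)
  expect_equal(m$left_angle, m$right_angle)
  expect_true(all(m$valid))

  # all-zero binary mask: a closed glottis, areas are valid zeros
  lm <- landmark_set(c(40, 10), c(40, 30))
  closed <- glottal_frame(matrix(0, 60, 80), c(1.5, 1.5), "phonation",
                          landmarks = lm)
  mc <- measure_frame(closed)
  expect_equal(mc$left_area, 0)
  expect_true(mc$valid[["left_area"]])
  expect_false(mc$valid[["left_angle"]])

  # rendered asymmetric frame matches the analytic polygon half-areas
  p <- kinematic_params(theta_resp = c(12, 30), angle_jitter_sd = 0)
  poly <- glottis_polygon(p, "respiration")
  mr <- measure_frame(render_frame(poly, mode = "mask"))
  raster_slack <- 20 * 1.5 # one pixel-row along the AP length, mm^2
  expect_equal(mr$left_area, poly$left_area, tolerance = raster_slack / poly$left_area)
  expect_equal(mr$right_area, poly$right_area, tolerance = raster_slack / poly$right_area)
})

test_that("period summary averages valid frames and conserves the total", {
  fr <- triangle_frame(c(20, 25))
  m <- measure_frame(fr)
  s <- period_summary(rep(list(m), 10))
  expect_equal(s$n_frames, 10)
  expect_equal(s$mean_left_area, m$left_area)
  expect_equal(s$total_area, s$mean_left_area + s$mean_right_area)

  m2 <- m; m2$left_area <- 2 * m$left_area; m2$right_area <- 2 * m$right_area
  s2 <- period_summary(list(m, m2))
  expect_equal(s2$mean_left_area, 1.5 * m$left_area)

  bad <- m; bad$valid[] <- FALSE; bad$left_area <- NA_real_
  s3 <- period_summary(c(rep(list(m), 9), list(bad)))
  expect_equal(s3$n_frames, 9)
  expect_equal(s3$mean_left_area, m$left_area)

  expect_error(period_summary(list(bad)), "empty period")
})

test_that("hemi-areas are invariant under grid-preserving rigid motions", {
  fr <- triangle_frame(c(17, 24))
  m0 <- measure_frame(fr)
  # integer-pixel translation
  img <- fr$image
  shifted <- matrix(0, nrow(img), ncol(img))
  shifted[11:nrow(img), 7:ncol(img)] <- img[1:(nrow(img) - 10), 1:(ncol(img) - 6)]
  lm <- fr$landmarks
  fr_t <- glottal_frame(shifted, fr$spacing, fr$task,
                        landmarks = landmark_set(lm$ac + c(6, 10), lm$pc + c(6, 10)))
  mt <- measure_frame(fr_t)
  expect_equal(mt$left_area, m0$left_area)
  expect_equal(mt$left_angle, m0$left_angle)
  # 180-degree rotation about the grid center (square spacing)
  rot <- img[nrow(img):1, ncol(img):1]
  flip_pt <- function(p) c(ncol(img) - 1 - p[1], nrow(img) - 1 - p[2])
  fr_r <- glottal_frame(rot, fr$spacing, fr$task,
                        landmarks = landmark_set(flip_pt(lm$ac), flip_pt(lm$pc)))
  mr <- measure_frame(fr_r)
  # rotating mask and landmarks together preserves laterality
  expect_equal(mr$left_area, m0$left_area)
  expect_equal(mr$right_angle, m0$right_angle)
})

test_that("hemi-areas are stable under arbitrary rigid motions at fine raster", {
  p <- kinematic_params(theta_resp = c(20, 28), angle_jitter_sd = 0)
  poly <- glottis_polygon(p, "respiration")
  sp <- 0.375
  base <- cbind(119.25 + poly$vertices[, "v"], 36 + poly$vertices[, "u"])
  ac <- c(119.25, 36); pc <- c(119.25, 56)
  rasterize <- function(verts, ac_mm, pc_mm) {
    nc <- round(240 / sp); nr <- round(180 / sp)
    cx <- (0:(nc - 1)) * sp; cy <- (0:(nr - 1)) * sp
    inside <- pracma::inpolygon(rep(cx, each = nr), rep(cy, times = nc),
                                verts[, 1], verts[, 2], boundary = FALSE)
    mask <- matrix(as.numeric(inside), nr, nc)
    lm <- landmark_set(ac_mm / sp, pc_mm / sp)
    c(unlist(hemi_areas(mask, lm, c(sp, sp))[1:2]),
      unlist(hemi_angles(mask, lm, c(sp, sp))[1:2]))
  }
  ref <- rasterize(base, ac, pc)
  set.seed(11)
  for (i in 1:5) {
    th <- runif(1, 0, 2 * pi); sh <- runif(2, -15, 15); ctr <- c(120, 90)
    Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    tr <- function(xy) sweep(sweep(xy, 2, ctr) %*% t(Rm), 2, -(ctr + sh))
    v <- tr(base)
    if (any(v[, 1] < 2 | v[, 1] > 237 | v[, 2] < 2 | v[, 2] > 177)) next
    out <- rasterize(v, as.vector(tr(matrix(ac, 1))), as.vector(tr(matrix(pc, 1))))
    expect_lt(max(abs(out[1:2] - ref[1:2])), 2.5) # mm^2, ~3% of the hemi-area
    expect_lt(max(abs(out[3:4] - ref[3:4])), 1.5) # degrees
  }
})

test_that("pixel-counted hemi-areas converge to the closed form as spacing shrinks", {
  theta <- c(20, 20)
  exact <- triangle_hemi_area(20)
  errs <- vapply(c(1.5, 0.75, 0.375), function(sp) {
    m <- measure_frame(triangle_frame(theta, sp = sp))
    max(abs(c(m$left_area, m$right_area) - exact))
  }, 1)
  expect_true(all(diff(errs) <= 0))
  expect_lt(errs[3], 1)
})
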