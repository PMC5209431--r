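# Synthetic cine generator: schedule, polygon ground truth, rendering,
# subject/cohort simulation and its repeatability mechanisms.

test_that("task schedule alternates 10-s blocks starting with phonation", {
  s <- task_schedule(50, 1.0)
  expect_equal(nrow(s), 50)
  expect_equal(sum(s$task == "phonation"), 30) # P,R,P,R,P
  expect_equal(sum(s$task == "respiration"), 20)
  expect_equal(s$task[1], "phonation")
  expect_equal(rle(s$task)$lengths, rep(10, 5))

  s2 <- task_schedule(10.001, 0.764)
  expect_equal(sum(s2$task == "phonation"), 13)

  expect_error(task_schedule(30, 0), "positive")
  expect_error(task_schedule(30, -1), "positive")
  expect_error(task_schedule(0.5, 1), "too short")
})

test_that("glottis polygon carries closed-form hemi-areas as ground truth", {
  p <- kinematic_params(theta_resp = c(20, 20), ap_length = 20,
                        angle_jitter_sd = 0)
  poly <- glottis_polygon(p, "respiration")
  expect_equal(poly$left_area, 72.79405, tolerance = 1e-6)
  expect_equal(poly$right_area, poly$left_area)

  # degenerate phonation: zero-area polygon
  p0 <- kinematic_params(theta_resp = c(20, 20), theta_phon = c(0, 0),
                         angle_jitter_sd = 0)
  poly0 <- glottis_polygon(p0, "phonation")
  expect_equal(poly0$left_area + poly0$right_area, 0)

  # a paralysed fold ignores the task
  pp <- kinematic_params(theta_resp = c(25, 25), theta_phon = c(25, 1),
                         paralysis = "left", fixed_angle = 25,
                         angle_jitter_sd = 0)
  pr <- glottis_polygon(pp, "respiration")
  pf <- glottis_polygon(pp, "phonation")
  expect_equal(pr$left_area, pf$left_area)

  expect_error(kinematic_params(theta_resp = c(10, 10), theta_phon = c(20, 20)))
})

test_that("rendering is deterministic and consistent with the analytic area", {
  p <- kinematic_params(theta_resp = c(24, 18), angle_jitter_sd = 0)
  poly <- glottis_polygon(p, "respiration")
  f1 <- render_frame(poly, mode = "intensity", noise_sd = 0.05, seed = 42)
  f2 <- render_frame(poly, mode = "intensity", noise_sd = 0.05, seed = 42)
  expect_identical(f1$image, f2$image)
  f3 <- render_frame(poly, mode = "intensity", noise_sd = 0.05, seed = 43)
  expect_false(identical(f1$image, f3$image))

  mask <- render_frame(poly, mode = "mask")
  counted <- sum(mask$image) * prod(mask$spacing)
  analytic <- poly$left_area + poly$right_area
  perimeter <- 2 * sqrt(400 + (20 * tan(c(24, 18) * pi / 180))^2) +
    sum(20 * tan(c(24, 18) * pi / 180))
  expect_lt(abs(counted - analytic), sum(perimeter) * 1.5)

  expect_error(render_frame(glottis_polygon(
    kinematic_params(theta_resp = c(55, 55), ap_length = 150,
                     angle_jitter_sd = 0), "respiration")),
    "field of view")
})

test_that("measuring noise-free rendered frames recovers the stored ground truth", {
  # phonation angles kept above the sub-pixel regime at 1.5 mm spacing
  p <- kinematic_params(theta_resp = c(25, 15), theta_phon = c(6, 5),
                        angle_jitter_sd = 0, elevation_shift_sd = 0)
  sim <- simulate_subject(p, studies = 1, readers = 1, master_seed = 3,
                          mode = "mask")
  m <- sim$measurements; g <- sim$ground_truth
  ok <- m$valid_left_area
  expect_true(all(ok))
  # raster error bounded by one pixel-row along the AP length
  expect_lt(max(abs(m$left_area - g$left_area)), 20 * 1.5)
  expect_lt(max(abs(m$right_area - g$right_area)), 20 * 1.5)
  ang_ok <- m$valid_left_angle & m$valid_right_angle
  expect_lt(max(abs(m$left_angle[ang_ok] - g$left_angle[ang_ok])), 1.5)
  expect_lt(max(abs(m$right_angle[ang_ok] - g$right_angle[ang_ok])), 1.5)
})

test_that("subject simulation is reproducible and respects the session design", {
  p <- kinematic_params(theta_resp = c(25, 25), theta_phon = c(2, 2))
  s1 <- simulate_subject(p, master_seed = 11)
  s2 <- simulate_subject(p, master_seed = 11)
  expect_identical(s1$measurements, s2$measurements)
  expect_false(identical(
    s1$measurements$left_area,
    simulate_subject(p, master_seed = 12)$measurements$left_area))

  # studies 1 and 2 share the session elevation offset; study 3 draws anew:
  # with jitter and reader noise off, per-frame truth differs only via jitter
  p0 <- kinematic_params(theta_resp = c(25, 25), theta_phon = c(5, 5),
                         angle_jitter_sd = 0, elevation_shift_sd = 2)
  s <- simulate_subject(p0, master_seed = 7)
  g <- s$ground_truth
  a1 <- g$left_angle[g$study == 1]
  a2 <- g$left_angle[g$study == 2]
  a3 <- g$left_angle[g$study == 3]
  expect_equal(a1, a2)
  expect_false(isTRUE(all.equal(a1, a3)))
})

test_that("ideal noise-free subjects give the expected abduction potentials", {
  # healthy: symmetric abduction, complete adduction
  ph <- kinematic_params(theta_resp = c(25, 25), theta_phon = c(0, 0),
                         angle_jitter_sd = 0, elevation_shift_sd = 0,
                         reader_noise_area = 0, reader_noise_angle = 0)
  mh <- metrics_from_measurements(
    simulate_subject(ph, studies = 1, readers = 1, master_seed = 1,
                     mode = "mask")$measurements)
  expect_equal(mh$vfap, 100)
  expect_equal(mh$vfra, 0, tolerance = 0.02)
  expect_true(is.na(mh$vfpa))

  # UVFP: immobile left fold, symmetric respiration, healthy fold closes
  pu <- kinematic_params(theta_resp = c(25, 25), theta_phon = c(25, 0),
                         paralysis = "left", fixed_angle = 25,
                         angle_jitter_sd = 0, elevation_shift_sd = 0)
  mu <- metrics_from_measurements(
    simulate_subject(pu, studies = 1, readers = 1, master_seed = 1,
                     mode = "mask")$measurements)
  expect_equal(mu$vfap, 50, tolerance = 0.5 / 50)
})

test_that("cohort simulation matches the study design", {
  d <- simulate_cohort(cohort_config(), master_seed = 21)
  expect_equal(nrow(d$subjects), 14)
  expect_equal(sum(d$subjects$cohort == "uvfp"), 9)
  expect_equal(sum(d$subjects$has_study3), 10) # 5 healthy + 5 patients
  # reader 2 reads study 1 only
  expect_setequal(unique(d$measurements$study[d$measurements$reader == 2]), 1)
  # 20 frames per (subject, study, reader)
  cnt <- table(d$measurements$subject, d$measurements$study,
               d$measurements$reader)
  expect_true(all(cnt %in% c(0, 20)))

  d2 <- simulate_cohort(cohort_config(), master_seed = 21)
  expect_identical(d$measurements, d2$measurements)
  d3 <- simulate_cohort(cohort_config(), master_seed = 22)
  expect_false(identical(d$measurements$left_area, d3$measurements$left_area))
  expect_identical(dim(d$measurements), dim(d3$measurements))

  # zero noise everywhere: healthy VFRa exactly 0
  quiet <- cohort_config(angle_jitter_sd = 0, elevation_shift_sd = 0,
                         reader_noise_area = 0, reader_noise_angle = 0)
  dq <- simulate_cohort(quiet, master_seed = 2)
  mq <- metrics_from_measurements(dq$measurements)
  mq <- merge(mq, dq$subjects[, c("subject", "cohort")], by = "subject")
  expect_true(all(mq$vfra[mq$cohort == "healthy"] == 0))
})

test_that("inter-reader agreement approaches 1 as reader noise vanishes", {
  iccs <- vapply(c(4, 0.5, 0), function(sdr) {
    d <- simulate_cohort(cohort_config(reader_noise_area = sdr,
                                       reader_noise_angle = sdr / 4),
                         master_seed = 31)
    met <- metrics_from_measurements(d$measurements)
    repeatability_icc(met, "ICC2")
    tab <- repeatability_icc(met, "ICC2")
    tab$icc[tab$metric == "vfap" & tab$comparison == "inter_reader"]
  }, 1)
  expect_true(all(diff(iccs) > 0))
  expect_equal(iccs[3], 1)
})
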