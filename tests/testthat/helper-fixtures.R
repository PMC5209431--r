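# Fixtures and independent oracles shared across the suite.

# Vertical-axis frame: mask built from explicit foreground pixel (x, y)
# pairs on an nr x nc grid (0-based pixel coordinates).
mask_from_pixels <- function(px, nr = 12, nc = 12) {
  m <- matrix(0, nr, nc)
  m[cbind(px[, 2] + 1, px[, 1] + 1)] <- 1
  m
}

# Triangle fixture used throughout: apex-at-AC glottis with given
# half-angles, rasterized at `sp` mm with the AC->PC axis vertical and
# midway between pixel columns.
triangle_frame <- function(theta = c(20, 20), sp = 1.5, task = "respiration",
                           ap_length = 20, jitter = c(0, 0)) {
  p <- kinematic_params(theta_resp = theta, ap_length = ap_length,
                        angle_jitter_sd = 0, elevation_shift_sd = 0)
  poly <- glottis_polygon(p, task, jitter = jitter)
  render_frame(poly, spacing = c(sp, sp),
               ac_px = c(120 / sp - 0.5, 36 / sp), task = task)
}

# Independent ICC oracle: mean squares straight from stats::aov on the
# long-format two-way layout, then the textbook single-measure formulas.
icc_oracle <- function(x, form = "ICC2") {
  n <- nrow(x); k <- ncol(x)
  long <- data.frame(y = as.vector(x),
                     subj = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(aov(y ~ subj + rater, data = long))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  switch(form,
         ICC2 = (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
         ICC3 = (msr - mse) / (msr + (k - 1) * mse),
         ICC1 = {
           ms1 <- summary(aov(y ~ subj, data = long))[[1]][["Mean Sq"]]
           (ms1[1] - ms1[2]) / (ms1[1] + (k - 1) * ms1[2])
         })
}

# Closed-form hemi-areas of the idealized glottis triangle.
triangle_hemi_area <- function(theta_deg, ap_length = 20)
  0.5 * ap_length^2 * tan(theta_deg * pi / 180)

# Random blob mask: union of a few filled discs, for property tests.
random_blob_mask <- function(nr = 40, nc = 40) {
  m <- matrix(0, nr, nc)
  xs <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  ys <- matrix(rep(0:(nr - 1), nc), nr, nc)
  for (b in seq_len(sample(1:3, 1))) {
    cx <- runif(1, 5, nc - 6); cy <- runif(1, 5, nr - 6); r <- runif(1, 2, 8)
    m[(xs - cx)^2 + (ys - cy)^2 <= r^2] <- 1
  }
  m
}
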