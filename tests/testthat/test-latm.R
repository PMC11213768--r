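test_that("calibration override follows the x1.45 / x0.5 rule exactly", {
  # neutral region: base is the inner point, limits scale from it
  eb <- effective_base(400, 400)
  expect_identical(eb$base_hu, 400)
  expect_false(eb$overridden)
  expect_identical(eb$lower_hu, 200)
  expect_identical(eb$upper_hu, 580)
  # above the ceiling: 600 > 1.45 * 400 = 580
  eb <- effective_base(600, 400)
  expect_true(eb$overridden)
  expect_identical(eb$base_hu, 400)
  # below the floor: 150 < 0.5 * 400 = 200
  eb <- effective_base(150, 400)
  expect_true(eb$overridden)
  expect_identical(eb$base_hu, 400)
  # grid spanning both branches and the neutral band; strict inequalities
  for (inner in c(150, 199.9, 200, 201, 399, 400, 579, 580, 581, 600)) {
    for (calib in c(300, 400, 500)) {
      eb <- effective_base(inner, calib)
      expected_override <- inner > 1.45 * calib || inner < 0.5 * calib
      expect_identical(eb$overridden, expected_override)
      base <- if (expected_override) calib else inner
      expect_identical(eb$base_hu, base)
      expect_identical(eb$lower_hu, 0.5 * base)
      expect_identical(eb$upper_hu, 1.45 * base)
    }
  }
  expect_error(effective_base(NA_real_, 400), "non-finite")
  expect_error(effective_base(400, -1), "positive")
})

test_that("inner-point attenuation averages over the centered disc", {
  cs <- synthetic_cross_section(function(x, y) rep(400, length(x)))
  expect_equal(inner_point_attenuation(cs, 0.3), 400)
  # disc radius -> 0 converges to the center pixel
  cs2 <- synthetic_cross_section(function(x, y) 300 + 100 * (x^2 + y^2 < 0.004))
  expect_equal(inner_point_attenuation(cs2, 0), 400)
  # half-and-half plane: pixel-count-weighted mean
  cs3 <- synthetic_cross_section(function(x, y) ifelse(x < 0, 300, 400))
  expect_equal(inner_point_attenuation(cs3, 1), 350, tolerance = 0.02)
})

test_that("lumen detection matches the linear-crossing oracle to 1e-9", {
  # frozen hand case: 400 below r = 2, then 50; lower limit 200; samples
  # bracket at 1.9 / 2.0 so the crossing is 1.9 + 0.1 * 200/350
  p <- step_profile(2, c(400, 50))
  out <- detect_lumen_radius(p, 400, 580, 200)
  expect_equal(out$radius, 1.9 + 0.1 * (400 - 200) / (400 - 50),
               tolerance = 1e-12)
  expect_equal(out$radius, 1.957142857142857, tolerance = 1e-9)
  expect_identical(out$flag, "ok")
  # no crossing anywhere: capped at the profile end
  out <- detect_lumen_radius(step_profile(99, c(400, 400)), 400, 580, 200)
  expect_identical(out$flag, "capped")
  expect_equal(out$radius, 4)
  # calcification onset caps the radius first: 400 then 800 from r = 1.5
  p <- step_profile(1.5, c(400, 800))
  out <- detect_lumen_radius(p, 400, 580, 200)
  expect_identical(out$flag, "calcium-limited")
  expect_equal(out$radius, 1.4 + 0.1 * (580 - 400) / (800 - 400),
               tolerance = 1e-12)
  expect_error(detect_lumen_radius(step_profile(2, c(400, 50)), 400, 300, 350),
               "limits")
})

test_that("lumen detection equals the closed-form crossing on random steps", {
  set.seed(42)
  for (rep in 1:50) {
    edge <- runif(1, 0.5, 3.5)
    inner <- runif(1, 300, 500)
    outer <- runif(1, -100, 150)
    p <- step_profile(edge, c(inner, outer))
    lower <- 0.5 * inner
    out <- detect_lumen_radius(p, inner, 1.45 * inner, lower)
    oracle <- crossing_oracle(p$radii, p$hu, lower)
    expect_equal(out$radius, oracle, tolerance = 1e-9)
  }
})

test_that("outer-wall detection finds the strongest eligible gradient", {
  # plaque 60 HU between 2 and 3 mm, background -50: wall edge at 3 mm
  p <- step_profile(c(2, 3), c(400, 60, -50), step = 0.05)
  dl <- detect_lumen_radius(p, 400, 580, 200)
  dv <- detect_vessel_radius(p, dl$radius, 400)
  expect_identical(dv$flag, "ok")
  expect_lt(abs(dv$radius - 3), 0.05 + 1e-12)  # within one radial step
  # constant at 0.4 * base beyond the lumen: no gradient peak at all
  p2 <- step_profile(2, c(400, 160), step = 0.05)
  dl2 <- detect_lumen_radius(p2, 400, 580, 200)
  dv2 <- detect_vessel_radius(p2, dl2$radius, 400)
  expect_identical(dv2$flag, "no-outer")
  expect_identical(dv2$radius, dl2$radius)
  # ordering always holds
  expect_gte(dv$radius, dl$radius)
  expect_error(detect_vessel_radius(p, 4, 400), "profile end")
})

test_that("calcified wall samples are ineligible as outer-wall spots", {
  # dense calcium (800 HU) in the wall: under partial-volume blur its edge
  # gradients peak at attenuations above the 0.5 * base ceiling, so the
  # wall spot must come from beyond the calcium
  p <- step_profile(c(2, 2.2, 2.8, 3.2), c(400, 60, 800, 60, -50), step = 0.02)
  p$hu <- latmseg:::smooth_gaussian_1d(p$hu, 0.08 / 0.02)
  dl <- detect_lumen_radius(p, 400, 580, 200)
  expect_identical(dl$flag, "ok")     # plaque shell separates lumen and calcium
  expect_lt(abs(dl$radius - 2.02), 0.05)
  dv <- detect_vessel_radius(p, dl$radius, 400)
  expect_identical(dv$flag, "ok")
  expect_gt(dv$radius, 2.9)
})

test_that("detected radii are invariant to a global attenuation rescale", {
  p <- step_profile(c(2, 3), c(420, 55, -40), step = 0.05)
  for (k in c(0.5, 2, 3.7)) {
    pk <- p; pk$hu <- p$hu * k
    a <- detect_lumen_radius(p, 420, 1.45 * 420, 0.5 * 420)
    b <- detect_lumen_radius(pk, 420 * k, 1.45 * 420 * k, 0.5 * 420 * k)
    expect_equal(a$radius, b$radius, tolerance = 1e-12)
    va <- detect_vessel_radius(p, a$radius, 420)
    vb <- detect_vessel_radius(pk, b$radius, 420 * k)
    expect_equal(va$radius, vb$radius, tolerance = 1e-12)
  }
})

test_that("a calcium arc never enlarges the detected lumen", {
  # same profile with and without an 800 HU calcium band outside the lumen
  base <- step_profile(c(2, 3), c(400, 60, -50), step = 0.05)
  for (ca_start in c(2.05, 2.3, 2.6)) {
    calc <- step_profile(c(2, ca_start, ca_start + 0.3, 3),
                         c(400, 60, 800, 60, -50), step = 0.05)
    r0 <- detect_lumen_radius(base, 400, 580, 200)$radius
    r1 <- detect_lumen_radius(calc, 400, 580, 200)$radius
    expect_lte(r1, r0 + 1e-12)
  }
})

test_that("plane segmentation recovers a concentric disc", {
  cs <- blurred_disc_cs(sigma = 0.15)
  cfg <- latm_config(calibration_hu = 400, median_filter = FALSE)
  ct <- segment_cross_section(cs, cfg)
  expect_identical(unique(ct$flags), "ok")
  # all rays within half a radial step of the closed-form crossing radius
  # (profile smoothing compounds with the disc blur: sigmas add in square)
  sigma_eff <- sqrt(0.15^2 + cfg$profile_smoothing_sigma^2)
  r_expected <- disc_lumen_crossing(200, sigma = sigma_eff)
  expect_lt(max(abs(ct$lumen_radii - r_expected)), cfg$radial_step / 2)
  # outer wall at the gradient peak (erf edge center is the true wall)
  expect_lt(max(abs(ct$vessel_radii - 3)), 2 * cfg$radial_step)
  # area ordering and containment
  expect_lte(polygon_area(ct$lumen_polygon), polygon_area(ct$vessel_polygon))
  expect_true(all(ct$vessel_radii >= ct$lumen_radii))
})

test_that("segmentation is rotation invariant within tolerance", {
  f <- function(x, y) {
    # slightly elliptical lumen to make orientation matter
    r <- sqrt((x / 1.1)^2 + (y / 0.9)^2)
    rw <- sqrt(x^2 + y^2)
    60 + 340 * pnorm((2 - r) / 0.15) - 110 * pnorm((rw - 3) / 0.15)
  }
  g <- function(x, y) f(-y, x)  # rotated by 90 degrees
  cfg <- latm_config(calibration_hu = 400)
  a <- segment_cross_section(synthetic_cross_section(f), cfg)
  b <- segment_cross_section(synthetic_cross_section(g), cfg)
  area_a <- polygon_area(a$lumen_polygon)
  area_b <- polygon_area(b$lumen_polygon)
  expect_lt(abs(area_a - area_b) / area_a, 0.005)
})

test_that("override neutrality: matching calibration changes nothing", {
  cs <- blurred_disc_cs()
  inner <- inner_point_attenuation(cs, 0.3)
  # calibration equal to the inner point: the override never triggers and
  # the contours are identical to a far-from-override calibration
  neutral <- segment_cross_section(cs, latm_config(calibration_hu = inner))
  other <- segment_cross_section(cs, latm_config(calibration_hu = inner * 1.2))
  expect_false(neutral$overridden)
  expect_false(other$overridden)
  expect_equal(neutral$base_hu, inner)
  expect_identical(neutral$lumen_radii, other$lumen_radii)
})

test_that("a plane with no boundary information fails loudly", {
  cs <- synthetic_cross_section(function(x, y) rep(400, length(x)))
  cfg <- latm_config(calibration_hu = 400)
  expect_error(segment_cross_section(cs, cfg), "segmentation failure")
})

test_that("ray median filtering suppresses single-ray outliers", {
  x <- rep(2, 32); x[10] <- 3.5
  expect_equal(latmseg:::median_filter_circular(x, 3), rep(2, 32))
})

test_that("whole-segment segmentation mirrors plane bookkeeping", {
  spec <- small_spec()
  ph <- make_vessel_phantom(spec)
  cfg <- latm_config(calibration_hu = 400)
  seg <- segment_vessel(ph$volume, ph$centerline, cfg, interval = 0.5)
  expect_equal(nrow(seg$profile) + nrow(seg$failed),
               floor(spec$segment_length / 0.5) + 1L)
  expect_equal(nrow(seg$failed), 0L)
  # near-constant profile away from the stenosis
  flat <- make_vessel_phantom(small_spec(stenosis_severity = 0))
  seg2 <- segment_vessel(flat$volume, flat$centerline, cfg, interval = 0.5)
  la <- seg2$profile$lumen_area_mm2
  expect_lt(stats::sd(la) / mean(la), 0.02)
  # vessel polygon contains every lumen vertex (star-convex ordering)
  ct <- seg$contours[[3L]]
  expect_true(all(ct$lumen_radii <= ct$vessel_radii + 1e-12))
})

test_that("a contrast-free segment raises a segment-level failure", {
  spec <- small_spec(lumen_hu = -50, plaque_hu = -50, noise_sd = 0)
  ph <- make_vessel_phantom(spec)
  cfg <- latm_config(calibration_hu = 400)
  expect_error(segment_vessel(ph$volume, ph$centerline, cfg, interval = 1),
               "segment-level")
})
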