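# Small phantoms and synthetic profiles used across tests. Kept compact so
# the unit suite stays fast; full-scale runs live in the acceptance tests.

small_spec <- function(...) {
  args <- list(segment_length = 8, stenosis_center = 4, stenosis_length = 4,
               base_lumen_radius = 2, base_vessel_radius = 3,
               noise_sd = 0, transverse_margin = 2.5, end_margin = 1.5)
  user <- list(...)
  args[names(user)] <- user
  do.call(phantom_spec, args)
}

# step radial profile: `levels[k]` between breaks[k-1] and breaks[k]
step_profile <- function(breaks, levels, step = 0.1, max_radius = 4,
                         angle = 0) {
  radii <- seq(0, max_radius, by = step)
  hu <- levels[findInterval(radii, breaks) + 1L]
  structure(list(radii = radii, hu = hu, angle = angle),
            class = "radial_profile")
}

# closed-form linear-interpolation crossing radius on a step profile
crossing_oracle <- function(radii, hu, level, upward = FALSE) {
  for (i in 2:length(hu)) {
    hit <- if (upward) hu[i] > level && hu[i - 1L] <= level
           else hu[i] < level && hu[i - 1L] >= level
    if (hit)
      return(radii[i - 1L] + (radii[i] - radii[i - 1L]) *
               (hu[i - 1L] - level) / (hu[i - 1L] - hu[i]))
  }
  Inf
}

# concentric blurred disc cross-section: lumen R1, wall R2, erf edges
blurred_disc_cs <- function(R1 = 2, R2 = 3, lumen = 400, plaque = 60,
                            background = -50, sigma = 0.15,
                            fov = 10, spacing = 0.1) {
  synthetic_cross_section(function(x, y) {
    r <- sqrt(x^2 + y^2)
    plaque + (lumen - plaque) * pnorm((R1 - r) / sigma) +
      (background - plaque) * pnorm((r - R2) / sigma)
  }, fov = fov, spacing = spacing)
}

# expected 50%-of-inner crossing radius for blurred_disc_cs geometry
disc_lumen_crossing <- function(level, R1 = 2, lumen = 400, plaque = 60,
                                sigma = 0.15) {
  # solve plaque + (lumen-plaque) * pnorm((R1-r)/sigma) = level
  R1 - sigma * qnorm((level - plaque) / (lumen - plaque))
}

interp_trilinear_at <- function(v, pt) {
  latmseg:::interp_trilinear(v$values, v$spacing, v$origin,
                             matrix(pt, ncol = 3L))$values
}

ramp_profile <- function(n = 21, interval = 0.5, la0 = 8, slope = 0.2,
                         va = 30) {
  s <- seq(0, by = interval, length.out = n)
  area_profile(s, la0 + slope * s, rep(va, n), interval = interval)
}
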