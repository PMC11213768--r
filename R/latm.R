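## Location-adaptive threshold boundary detection.
##
## Per cross-sectional plane, attenuation limits scale with the local
## inner-point attenuation: the lumen boundary is the first outward
## crossing of the 50% lower limit (full-width-at-half-maximum style), a
## crossing of the 145% upper limit marks calcification onset and caps the
## lumen radius, and the outer vessel wall is the strongest attenuation
## gradient whose attenuation lies below 50% of the base. When the inner
## point deviates from the calibration attenuation by more than the same
## x1.45 / x0.5 factors, the calibration factor replaces the inner point as
## the base for both limits.

#' Configuration of the location-adaptive threshold method
#'
#' @param calibration_hu reference attenuation (HU) standing in for an
#'   aorta-derived calibration factor; must be positive.
#' @param upper_ratio upper limit as a multiple of the base attenuation
#'   (default 1.45; attenuation above it is treated as calcification).
#' @param lower_ratio lower limit as a multiple of the base attenuation
#'   (default 0.5, the full-width-at-half-maximum level).
#' @param n_rays number of equally spaced radial search directions.
#' @param radial_step radial sampling step, mm.
#' @param max_radius maximal search radius, mm.
#' @param inner_disc_radius radius (mm) of the disc over which the
#'   inner-point attenuation is averaged (stabilizes against noise).
#' @param profile_smoothing_sigma Gaussian smoothing of each radial
#'   attenuation profile, mm (0 disables).
#' @param median_filter apply a circular window-3 median filter across
#'   adjacent rays' radii to suppress single-ray outliers.
#' @return An object of class `latm_config`.
#' @export
latm_config <- function(calibration_hu,
                        upper_ratio = 1.45, lower_ratio = 0.5,
                        n_rays = 64L, radial_step = 0.05,
                        max_radius = 4.0, inner_disc_radius = 0.3,
                        profile_smoothing_sigma = 0.1,
                        median_filter = TRUE) {
  if (!is.finite(calibration_hu) || calibration_hu <= 0)
    stopf("calibration_hu must be positive")
  if (!(lower_ratio > 0 && lower_ratio < 1 && upper_ratio > 1))
    stopf("need 0 < lower_ratio < 1 < upper_ratio")
  if (n_rays < 8L) stopf("n_rays must be >= 8")
  if (radial_step <= 0) stopf("radial_step must be positive")
  if (max_radius <= inner_disc_radius)
    stopf("max_radius must exceed inner_disc_radius")
  structure(list(calibration_hu = calibration_hu,
                 upper_ratio = upper_ratio, lower_ratio = lower_ratio,
                 n_rays = as.integer(n_rays), radial_step = radial_step,
                 max_radius = max_radius,
                 inner_disc_radius = inner_disc_radius,
                 profile_smoothing_sigma = profile_smoothing_sigma,
                 median_filter = isTRUE(median_filter)),
            class = "latm_config")
}

#' Inner-point attenuation of a cross-section
#'
#' Mean attenuation over the disc of radius `disc_radius` centered at the
#' centerline point of the plane. Flagged (out-of-volume) pixels are
#' excluded.
#'
#' @param cs a `cross_section`.
#' @param disc_radius disc radius, mm.
#' @return mean attenuation, HU.
#' @export
inner_point_attenuation <- function(cs, disc_radius = 0.3) {
  if (disc_radius < 0) stopf("disc_radius must be >= 0")
  d <- dim(cs$grid)
  ci <- cs$center_index
  sp <- cs$in_plane_spacing
  dx <- (seq_len(d[1L]) - ci[1L]) * sp
  dy <- (seq_len(d[2L]) - ci[2L]) * sp
  inside <- outer(dx^2, dy^2, `+`) <= disc_radius^2
  inside <- inside & !cs$oob
  if (!any(inside)) stopf("empty inner disc")
  mean(cs$grid[inside])
}

#' Effective base attenuation with calibration override
#'
#' The base for the threshold limits is the inner-point attenuation, unless
#' the inner point deviates strongly from the calibration attenuation
#' (`inner > 1.45 * calibration` or `inner < 0.5 * calibration`), in which
#' case the calibration factor is used instead. The limits then derive as
#' `lower_ratio * base` and `upper_ratio * base`.
#'
#' @param inner_hu inner-point attenuation, HU.
#' @param calibration_hu calibration attenuation, HU (> 0).
#' @param upper_ratio,lower_ratio the override/limit ratios.
#' @return list with `base_hu`, `overridden`, `lower_hu`, `upper_hu`.
#' @export
effective_base <- function(inner_hu, calibration_hu,
                           upper_ratio = 1.45, lower_ratio = 0.5) {
  if (!is.finite(inner_hu) || !is.finite(calibration_hu))
    stopf("non-finite attenuation input")
  if (calibration_hu <= 0) stopf("calibration_hu must be positive")
  overridden <- inner_hu > upper_ratio * calibration_hu ||
                inner_hu < lower_ratio * calibration_hu
  base <- if (overridden) calibration_hu else inner_hu
  list(base_hu = base, overridden = overridden,
       lower_hu = lower_ratio * base, upper_hu = upper_ratio * base)
}

#' Radial attenuation profile of a cross-section
#'
#' Bilinear samples along a ray from the plane center outward, optionally
#' Gaussian-smoothed. The profile is truncated at the first out-of-volume
#' sample.
#'
#' @param cs a `cross_section`.
#' @param angle ray direction, radians (in the plane basis).
#' @param step radial step, mm.
#' @param max_radius maximal radius, mm.
#' @param smoothing_sigma Gaussian smoothing of the profile, mm (0 = none).
#' @return object of class `radial_profile`: `radii` (mm, ascending from
#'   0), `hu`, `angle`.
#' @export
radial_profile <- function(cs, angle, step = 0.05, max_radius = 4.0,
                           smoothing_sigma = 0) {
  if (step <= 0) stopf("step must be positive")
  radii <- seq(0, by = step, length.out = floor(max_radius / step + 1e-9) + 1L)
  sp <- cs$in_plane_spacing
  px <- (cs$center_index[1L] - 1L) + radii * cos(angle) / sp
  py <- (cs$center_index[2L] - 1L) + radii * sin(angle) / sp
  res <- interp_bilinear(cs$grid, px, py)
  bad <- res$oob
  ## flagged (out-of-volume) pixels poison the interpolated sample
  fl <- interp_bilinear(cs$oob * 1, px, py)
  bad <- bad | (fl$values > 0 & !is.na(fl$values))
  hu <- res$values
  if (any(bad)) {
    first_bad <- which(bad)[1L]
    if (first_bad <= 2L) stopf("ray leaves the sampled grid immediately")
    hu <- hu[seq_len(first_bad - 1L)]
    radii <- radii[seq_len(first_bad - 1L)]
  }
  if (smoothing_sigma > 0) hu <- smooth_gaussian_1d(hu, smoothing_sigma / step)
  structure(list(radii = radii, hu = hu, angle = angle),
            class = "radial_profile")
}

## first index i >= 2 with a downward (or upward) crossing of `level`
first_crossing <- function(hu, level, upward = FALSE) {
  n <- length(hu)
  if (upward) idx <- which(hu[-1L] > level & hu[-n] <= level)
  else idx <- which(hu[-1L] < level & hu[-n] >= level)
  if (length(idx) == 0L) return(NULL)
  i <- idx[1L] + 1L
  list(i = i, delta = abs(hu[i] - hu[i - 1L]))
}

#' Detect the lumen radius on one radial profile
#'
#' The lumen boundary is the first outward crossing below the lower limit
#' (full-width-at-half-maximum style), located to sub-step precision by
#' linear interpolation between the bracketing samples. A crossing above
#' the upper limit (calcification onset) caps the radius first if it occurs
#' earlier. If both events fall in the same step window, the one with the
#' larger attenuation change between bracketing samples wins (tie: smaller
#' radius). With no event before the end of the profile, the radius is
#' capped at the last sample.
#'
#' @param p a `radial_profile`.
#' @param base_hu effective base attenuation, HU.
#' @param upper_hu,lower_hu attenuation limits, HU (`lower_hu < base_hu <
#'   upper_hu`).
#' @return list with `radius` (mm) and `flag` ("ok", "calcium-limited" or
#'   "capped").
#' @export
detect_lumen_radius <- function(p, base_hu, upper_hu, lower_hu) {
  hu <- p$hu; radii <- p$radii
  if (length(hu) < 2L) stopf("profile has fewer than 2 samples")
  if (!(lower_hu < base_hu && base_hu < upper_hu))
    stopf("limits must satisfy lower_hu < base_hu < upper_hu")
  lo <- first_crossing(hu, lower_hu, upward = FALSE)
  ca <- first_crossing(hu, upper_hu, upward = TRUE)
  cross_r <- function(ev, level) {
    i <- ev$i
    radii[i - 1L] + (radii[i] - radii[i - 1L]) *
      (hu[i - 1L] - level) / (hu[i - 1L] - hu[i])
  }
  if (is.null(lo) && is.null(ca))
    return(list(radius = radii[length(radii)], flag = "capped"))
  if (!is.null(lo) && !is.null(ca) && lo$i == ca$i) {
    ## both crossings inside one step window: larger attenuation change
    ## wins; tie broken toward the smaller radius
    r_lo <- cross_r(lo, lower_hu); r_ca <- cross_r(ca, upper_hu)
    if (lo$delta > ca$delta || (lo$delta == ca$delta && r_lo <= r_ca))
      return(list(radius = r_lo, flag = "ok"))
    return(list(radius = r_ca, flag = "calcium-limited"))
  }
  r_lo <- if (is.null(lo)) Inf else cross_r(lo, lower_hu)
  r_ca <- if (is.null(ca)) Inf else cross_r(ca, upper_hu)
  if (r_lo <= r_ca) list(radius = r_lo, flag = "ok")
  else list(radius = r_ca, flag = "calcium-limited")
}

#' Detect the outer vessel radius on one radial profile
#'
#' Searching outward from the lumen radius, candidate wall positions are
#' local maxima of the absolute radial attenuation gradient (central
#' differences); the selected spot is the candidate with the largest
#' gradient magnitude whose attenuation lies below `0.5 * base_hu`
#' (calcified or still-enhanced samples are ineligible). The position is
#' refined to sub-step precision by a parabolic fit of the gradient peak.
#' With no qualifying candidate the wall collapses onto the lumen boundary
#' (flag "no-outer").
#'
#' @param p a `radial_profile`.
#' @param lumen_radius detected lumen radius, mm (must be below the profile
#'   end).
#' @param base_hu effective base attenuation, HU.
#' @return list with `radius` (mm) and `flag` ("ok" or "no-outer").
#' @export
detect_vessel_radius <- function(p, lumen_radius, base_hu) {
  hu <- p$hu; radii <- p$radii
  n <- length(hu)
  if (lumen_radius >= radii[n]) stopf("lumen radius reaches the profile end")
  if (n < 3L) return(list(radius = lumen_radius, flag = "no-outer"))
  step <- radii[2L] - radii[1L]
  g <- c(NA_real_, (hu[3:n] - hu[1:(n - 2L)]) / (radii[3:n] - radii[1:(n - 2L)]),
         NA_real_)
  ag <- abs(g)
  ceiling_hu <- 0.5 * base_hu
  ## local maxima of |gradient|; plateaus resolved toward the smaller radius
  agv <- ag; agv[is.na(agv)] <- -Inf
  left <- c(-Inf, agv[-n]); right <- c(agv[-1L], -Inf)
  cand <- which(agv > left & agv >= right & is.finite(agv))
  cand <- cand[radii[cand] > lumen_radius & hu[cand] < ceiling_hu & ag[cand] > 0]
  if (length(cand) == 0L) return(list(radius = lumen_radius, flag = "no-outer"))
  i <- cand[which.max(ag[cand])]
  ## parabolic sub-step refinement of the |gradient| peak
  r <- radii[i]
  if (i >= 3L && i <= n - 2L && !is.na(ag[i - 1L]) && !is.na(ag[i + 1L])) {
    den <- ag[i - 1L] - 2 * ag[i] + ag[i + 1L]
    if (is.finite(den) && den < 0) {
      delta <- 0.5 * (ag[i - 1L] - ag[i + 1L]) / den
      r <- r + max(-0.5, min(0.5, delta)) * step
    }
  }
  list(radius = max(r, lumen_radius), flag = "ok")
}

#' Segment one cross-sectional plane
#'
#' Computes the inner-point attenuation, applies the calibration override,
#' then detects per-ray lumen and outer-vessel radii over `n_rays` equally
#' spaced directions; radii are optionally median-filtered across adjacent
#' rays and assembled into closed boundary polygons (in-plane mm, centered
#' at the centerline point).
#'
#' @param cs a `cross_section`.
#' @param cfg a `latm_config`.
#' @return object of class `contour_pair`: `lumen_radii`, `vessel_radii`
#'   (per ray, mm), `angles`, `lumen_polygon`, `vessel_polygon` (closed
#'   n+1 x 2 matrices, mm), `flags` (per ray), `inner_hu`, `base_hu`,
#'   `overridden`, `s`.
#' @export
segment_cross_section <- function(cs, cfg) {
  if (!inherits(cs, "cross_section")) stopf("expected a cross_section")
  if (!inherits(cfg, "latm_config")) stopf("expected a latm_config")
  inner <- inner_point_attenuation(cs, cfg$inner_disc_radius)
  eb <- effective_base(inner, cfg$calibration_hu,
                       cfg$upper_ratio, cfg$lower_ratio)
  angles <- 2 * pi * (seq_len(cfg$n_rays) - 1L) / cfg$n_rays
  lum <- numeric(cfg$n_rays); ves <- numeric(cfg$n_rays)
  flags <- character(cfg$n_rays)
  for (k in seq_len(cfg$n_rays)) {
    prof <- radial_profile(cs, angles[k], step = cfg$radial_step,
                           max_radius = cfg$max_radius,
                           smoothing_sigma = cfg$profile_smoothing_sigma)
    dl <- detect_lumen_radius(prof, eb$base_hu, eb$upper_hu, eb$lower_hu)
    lum[k] <- dl$radius
    flags[k] <- dl$flag
    if (dl$flag == "capped" || dl$radius >= prof$radii[length(prof$radii)]) {
      ves[k] <- dl$radius
    } else {
      dv <- detect_vessel_radius(prof, dl$radius, eb$base_hu)
      ves[k] <- dv$radius
      if (dv$flag == "no-outer" && flags[k] == "ok") flags[k] <- "no-outer"
    }
  }
  if (all(flags == "capped"))
    stopf("segmentation failure: no boundary found on any ray (plane s = %s)",
          format(cs$s))
  if (cfg$median_filter) {
    lum <- median_filter_circular(lum, 3L)
    ves <- median_filter_circular(ves, 3L)
  }
  ves <- pmax(ves, lum)
  poly <- function(r) {
    p <- cbind(r * cos(angles), r * sin(angles))
    rbind(p, p[1L, , drop = FALSE])
  }
  structure(list(lumen_radii = lum, vessel_radii = ves, angles = angles,
                 lumen_polygon = poly(lum), vessel_polygon = poly(ves),
                 flags = flags, inner_hu = inner, base_hu = eb$base_hu,
                 overridden = eb$overridden, s = cs$s),
            class = "contour_pair")
}

#' @export
print.contour_pair <- function(x, ...) {
  cat(sprintf("<contour_pair> s=%s mm, lumen r %.2f-%.2f mm, vessel r %.2f-%.2f mm, base %.0f HU%s\n",
              format(x$s), min(x$lumen_radii), max(x$lumen_radii),
              min(x$vessel_radii), max(x$vessel_radii), x$base_hu,
              if (x$overridden) " (calibration override)" else ""))
  invisible(x)
}

#' Segment a vessel segment along its centerline
#'
#' Resamples the centerline at `interval`, builds rotation-minimizing
#' plane bases, extracts and segments every cross-sectional plane, and
#' stacks the contours into a 3D model. Planes on which segmentation fails
#' are excluded from the area profile and counted; more than 50% failed
#' planes is a segment-level failure.
#'
#' @param v an `hu_volume`.
#' @param c a `centerline` inside the volume.
#' @param cfg a `latm_config`.
#' @param interval plane spacing, mm (clinical platforms use 0.2-0.5 mm).
#' @param fov,in_plane_spacing in-plane sampling of each plane, mm.
#' @return list with `profile` (an [area_profile()]), `model` (a
#'   `stacked_model`: per-plane contours in world coordinates), `contours`
#'   (list of `contour_pair`), `failed` (data.frame of failed planes).
#' @export
segment_vessel <- function(v, c, cfg, interval = 0.25,
                           fov = 10, in_plane_spacing = 0.1) {
  cl <- resample_centerline(c, interval)
  fb <- plane_basis(cl$tangents, cl$points)
  n <- nrow(cl$points)
  contours <- vector("list", n)
  failed <- character(0); failed_s <- numeric(0)
  for (i in seq_len(n)) {
    cs <- extract_cross_section(v, cl$points[i, ],
                                list(e1 = fb$e1[i, ], e2 = fb$e2[i, ]),
                                fov = fov, spacing = in_plane_spacing,
                                s = cl$arclength[i])
    res <- tryCatch(segment_cross_section(cs, cfg), error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, conditionMessage(res))
      failed_s <- c(failed_s, cl$arclength[i])
      contours[i] <- list(NULL)
    } else contours[[i]] <- res
  }
  ok <- !vapply(contours, is.null, logical(1))
  if (sum(!ok) > n / 2)
    stopf("segment-level segmentation failure: %d of %d planes failed",
          sum(!ok), n)
  la <- vapply(contours[ok], function(ct) polygon_area(ct$lumen_polygon),
               numeric(1))
  va <- vapply(contours[ok], function(ct) polygon_area(ct$vessel_polygon),
               numeric(1))
  prof <- area_profile(positions = cl$arclength[ok], lumen_area = la,
                       vessel_area = va, interval = interval)
  model <- stacked_model(contours[ok], cl, fb, which(ok))
  list(profile = prof, model = model, contours = contours[ok],
       failed = data.frame(s_mm = failed_s,
                           message = failed, stringsAsFactors = FALSE))
}

## stack per-plane contours into world-coordinate rings
stacked_model <- function(contours, cl, fb, idx) {
  rings <- lapply(seq_along(contours), function(j) {
    i <- idx[j]; ct <- contours[[j]]
    e1 <- fb$e1[i, ]; e2 <- fb$e2[i, ]; p0 <- cl$points[i, ]
    ring <- function(r) {
      cbind(p0[1L] + r * cos(ct$angles) * e1[1L] + r * sin(ct$angles) * e2[1L],
            p0[2L] + r * cos(ct$angles) * e1[2L] + r * sin(ct$angles) * e2[2L],
            p0[3L] + r * cos(ct$angles) * e1[3L] + r * sin(ct$angles) * e2[3L])
    }
    list(s = ct$s, lumen = ring(ct$lumen_radii), vessel = ring(ct$vessel_radii))
  })
  structure(list(rings = rings), class = "stacked_model")
}

#' @export
print.stacked_model <- function(x, ...) {
  cat(sprintf("<stacked_model> %d contour planes\n", length(x$rings)))
  invisible(x)
}
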