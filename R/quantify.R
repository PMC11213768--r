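## Area, burden and volume quantification, and interval-adaptive profile
## matching between a test measurement and a fine-interval reference.

#' Per-plane area profile along a vessel segment
#'
#' Plaque area is derived as `vessel_area - lumen_area` and burden as
#' `plaque / vessel`, so the identity survives any downstream resampling.
#' Positions are normally uniformly spaced at `interval`; gaps are
#' tolerated (planes excluded for segmentation failure) but volume
#' operators then refuse the profile.
#'
#' @param positions arclengths, mm (strictly increasing).
#' @param lumen_area,vessel_area areas, mm^2 (`lumen <= vessel`).
#' @param interval nominal plane spacing, mm.
#' @return object of class `area_profile` (also a data.frame) with columns
#'   `s_mm`, `lumen_area_mm2`, `vessel_area_mm2`, `plaque_area_mm2`,
#'   `plaque_burden`, and attribute `interval`.
#' @export
area_profile <- function(positions, lumen_area, vessel_area, interval) {
  n <- length(positions)
  if (n < 1L) stopf("empty area profile")
  if (length(lumen_area) != n || length(vessel_area) != n)
    stopf("positions and areas must have equal length")
  if (n > 1L && any(diff(positions) <= 0))
    stopf("positions must be strictly increasing")
  if (any(vessel_area <= 0)) stopf("vessel areas must be positive")
  if (any(lumen_area < 0) || any(lumen_area > vessel_area + 1e-9))
    stopf("need 0 <= lumen_area <= vessel_area")
  plaque <- pmax(vessel_area - lumen_area, 0)
  df <- data.frame(s_mm = positions,
                   lumen_area_mm2 = lumen_area,
                   vessel_area_mm2 = vessel_area,
                   plaque_area_mm2 = plaque,
                   plaque_burden = plaque / vessel_area)
  structure(df, interval = interval,
            class = c("area_profile", "data.frame"))
}

profile_uniform <- function(profile, tol = 1e-9) {
  n <- nrow(profile)
  if (n < 2L) return(TRUE)
  d <- diff(profile$s_mm)
  iv <- attr(profile, "interval")
  max(abs(d - iv)) <= tol * max(1, iv)
}

area_column <- function(which = c("lumen", "plaque", "vessel")) {
  which <- match.arg(which)
  paste0(which, "_area_mm2")
}

#' Area of a simple closed polygon (shoelace formula)
#'
#' @param points n x 2 matrix of vertices, mm; the polygon may be given
#'   open or closed (first vertex repeated). Must be simple.
#' @param check test for self-intersection (O(n^2); on by default).
#' @return absolute area, mm^2.
#' @export
polygon_area <- function(points, check = TRUE) {
  points <- matrix(as.numeric(points), ncol = 2L)
  n <- nrow(points)
  if (n >= 2L && all(abs(points[n, ] - points[1L, ]) < 1e-12)) {
    points <- points[-n, , drop = FALSE]
    n <- n - 1L
  }
  if (n < 3L) stopf("polygon needs at least 3 distinct vertices")
  if (check && polygon_self_intersects(points)) stopf("self-intersecting polygon")
  x <- points[, 1L]; y <- points[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  abs(sum(x * yn - xn * y)) / 2
}

## segment-pair intersection test over non-adjacent edges
polygon_self_intersects <- function(p) {
  n <- nrow(p)
  a <- p; b <- p[c(2:n, 1L), , drop = FALSE]
  cross2 <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    j <- seq.int(i + 2L, n)
    if (i == 1L) j <- j[j != n]  # skip adjacent wrap-around edge
    if (length(j) == 0L) next
    d1 <- cross2(a[i, 1L], a[i, 2L], b[i, 1L], b[i, 2L], a[j, 1L], a[j, 2L])
    d2 <- cross2(a[i, 1L], a[i, 2L], b[i, 1L], b[i, 2L], b[j, 1L], b[j, 2L])
    d3 <- cross2(a[j, 1L], a[j, 2L], b[j, 1L], b[j, 2L], a[i, 1L], a[i, 2L])
    d4 <- cross2(a[j, 1L], a[j, 2L], b[j, 1L], b[j, 2L], b[i, 1L], b[i, 2L])
    hit <- (d1 * d2 < 0) & (d3 * d4 < 0)
    if (any(hit)) return(TRUE)
  }
  FALSE
}

#' Plaque burden
#'
#' Ratio of plaque area to vessel area. Burden above 0.6 defines the
#' stenotic subgroup.
#'
#' @param plaque_area,vessel_area areas, mm^2.
#' @return burden fraction in [0, 1].
#' @export
plaque_burden <- function(plaque_area, vessel_area) {
  if (any(vessel_area <= 0)) stopf("vessel_area must be positive")
  if (any(plaque_area < 0) || any(plaque_area > vessel_area))
    stopf("need 0 <= plaque_area <= vessel_area")
  plaque_area / vessel_area
}

#' Volume as area sum times interval
#'
#' `sum(areas) * interval`: the convention of the clinical software
#' platforms (areas per plane at a fixed interval).
#'
#' @param profile an `area_profile` with uniform spacing.
#' @param which `"lumen"`, `"plaque"` or `"vessel"`.
#' @return volume, mm^3.
#' @export
volume_sum <- function(profile, which = c("lumen", "plaque", "vessel")) {
  if (nrow(profile) < 1L) stopf("empty profile")
  if (!profile_uniform(profile))
    stopf("profile spacing is not uniform (excluded planes?); cannot integrate")
  sum(profile[[area_column(which)]]) * attr(profile, "interval")
}

#' Volume by composite Simpson integration
#'
#' Composite Simpson's rule over the area profile (trapezoid on a trailing
#' odd panel when the plane count is even): the convention of
#' intravascular-ultrasound volume analysis.
#'
#' @inheritParams volume_sum
#' @return volume, mm^3.
#' @export
volume_simpson <- function(profile, which = c("lumen", "plaque", "vessel")) {
  if (nrow(profile) < 3L) stopf("Simpson integration needs at least 3 planes")
  if (!profile_uniform(profile))
    stopf("profile spacing is not uniform (excluded planes?); cannot integrate")
  simpson_integral(profile[[area_column(which)]], attr(profile, "interval"))
}

#' Resample an area profile at given positions
#'
#' Linear interpolation of the lumen and vessel area channels; plaque area
#' and burden are recomputed from the interpolated areas so that
#' `plaque = vessel - lumen` survives resampling. Extrapolation is refused.
#'
#' @param fine source `area_profile` (e.g. the fine-interval reference).
#' @param target_positions arclengths, mm, within the source range.
#' @return an `area_profile` at the target positions.
#' @export
resample_profile <- function(fine, target_positions) {
  rng <- range(fine$s_mm)
  if (any(target_positions < rng[1L] - 1e-9 | target_positions > rng[2L] + 1e-9))
    stopf("target positions extrapolate beyond the profile range [%g, %g] mm",
          rng[1L], rng[2L])
  la <- stats::approx(fine$s_mm, fine$lumen_area_mm2, xout = target_positions)$y
  va <- stats::approx(fine$s_mm, fine$vessel_area_mm2, xout = target_positions)$y
  d <- diff(target_positions)
  iv <- if (length(d) > 0L && max(abs(d - d[1L])) < 1e-9) d[1L] else NA_real_
  area_profile(target_positions, la, va, interval = iv)
}

#' Paired test/reference measurements
#'
#' @param test,reference equal-length numeric vectors.
#' @param label free-text label (e.g. `"lumen_area"`).
#' @param positions optional matched arclengths, mm.
#' @return object of class `paired_measurements`.
#' @export
paired_measurements <- function(test, reference, label = "",
                                positions = NULL) {
  if (length(test) != length(reference))
    stopf("test and reference must have equal length")
  structure(list(test = as.numeric(test), reference = as.numeric(reference),
                 n = length(test), label = label, positions = positions),
            class = "paired_measurements")
}

#' @export
print.paired_measurements <- function(x, ...) {
  cat(sprintf("<paired_measurements> %s: n=%d, bias %.3f\n",
              if (nzchar(x$label)) x$label else "(unlabeled)", x$n,
              mean(x$test - x$reference)))
  invisible(x)
}

#' Align a test profile with a reference profile and pair the planes
#'
#' The reference (typically the fine-interval pullback profile) is shifted
#' by `offset` along arclength, then resampled at the test profile's plane
#' positions. Landmark alignment in practice is such a signed scalar
#' offset. Test planes outside the overlap are dropped (their count is
#' recorded in the `dropped` attribute).
#'
#' @param test,reference `area_profile`s.
#' @param offset arclength shift applied to the reference, mm.
#' @param which `"lumen"`, `"plaque"` or `"vessel"`.
#' @return a `paired_measurements` (attribute `dropped` = planes outside
#'   the overlap, attribute `reference_burden` = reference plaque burden at
#'   the paired positions).
#' @export
align_and_pair <- function(test, reference, offset = 0,
                           which = c("lumen", "plaque", "vessel")) {
  col <- area_column(which)
  ref_s <- reference$s_mm + offset
  keep <- test$s_mm >= min(ref_s) - 1e-9 & test$s_mm <= max(ref_s) + 1e-9
  if (!any(keep)) stopf("no overlap between test and reference profiles")
  pos <- test$s_mm[keep]
  ref_at <- resample_profile(
    area_profile(ref_s, reference$lumen_area_mm2, reference$vessel_area_mm2,
                 interval = attr(reference, "interval")),
    pos)
  pm <- paired_measurements(test[[col]][keep], ref_at[[col]],
                            label = paste0(which, "_area"), positions = pos)
  attr(pm, "dropped") <- sum(!keep)
  attr(pm, "reference_burden") <- ref_at$plaque_burden
  pm
}

#' Stenotic-subgroup subset of paired measurements
#'
#' Retains the planes whose reference plaque burden strictly exceeds the
#' threshold (default 0.6, the stenotic-region criterion; a burden exactly
#' at the threshold is excluded).
#'
#' @param pairs a `paired_measurements`.
#' @param burden reference per-plane burden, aligned with `pairs`.
#' @param threshold burden threshold in (0, 1).
#' @return a `paired_measurements` restricted to the stenotic planes.
#' @export
stenotic_subset <- function(pairs, burden, threshold = 0.6) {
  if (length(burden) != pairs$n)
    stopf("burden vector length (%d) does not match pairs (%d)",
          length(burden), pairs$n)
  if (!(threshold > 0 && threshold < 1)) stopf("threshold must lie in (0, 1)")
  keep <- burden > threshold
  paired_measurements(pairs$test[keep], pairs$reference[keep],
                      label = paste0(pairs$label, "_stenotic"),
                      positions = pairs$positions[keep])
}
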