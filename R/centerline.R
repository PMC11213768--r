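## Centerlines and curved planar reformation.
##
## A centerline is an ordered polyline in world coordinates (mm) with
## cumulative arclength and unit tangents. Cross-sectional planes are
## spanned by rotation-minimizing frames so that the in-plane orientation
## varies smoothly even across straight runs (where Frenet frames are
## undefined).

#' Construct an attenuation volume
#'
#' Container for a 3D CT attenuation grid. The world position of voxel
#' (i, j, k) (0-based) is `origin + c(i, j, k) * spacing`; axes are assumed
#' axis-aligned with the world frame.
#'
#' @param values 3D numeric array of attenuation values (HU).
#' @param spacing voxel spacing in mm, length 3 (or scalar, recycled).
#' @param origin world coordinates (mm) of the first voxel center.
#' @return An object of class `hu_volume`.
#' @export
hu_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L) stopf("values must be a 3D array")
  if (any(dim(values) < 2L)) stopf("volume must have at least 2 voxels per axis")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("voxel spacing must be positive and finite")
  if (any(!is.finite(values))) stopf("attenuation values must be finite")
  structure(list(values = values, spacing = spacing,
                 origin = rep_len(as.numeric(origin), 3L)),
            class = "hu_volume")
}

#' @export
print.hu_volume <- function(x, ...) {
  cat(sprintf("<hu_volume> %s voxels, spacing %s mm, HU range [%.1f, %.1f]\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing, digits = 4), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Construct a centerline from ordered world points
#'
#' Arclength is the cumulative chord length starting at 0; unit tangents are
#' computed by central differences (one-sided at the ends).
#'
#' @param points n x 3 matrix of ordered world coordinates (mm), n >= 2.
#' @return An object of class `centerline` with fields `points`,
#'   `arclength`, `tangents`, `interval` (mean point spacing, mm).
#' @export
centerline <- function(points) {
  points <- matrix(as.numeric(points), ncol = 3L)
  n <- nrow(points)
  if (n < 2L) stopf("a centerline needs at least 2 points")
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                       points[-n, , drop = FALSE])^2))
  if (any(seg <= 0)) stopf("centerline points must be strictly ordered (duplicate point)")
  arclength <- c(0, cumsum(seg))
  tangents <- matrix(0, n, 3L)
  tangents[1L, ] <- points[2L, ] - points[1L, ]
  tangents[n, ] <- points[n, ] - points[n - 1L, ]
  if (n > 2L)
    tangents[2:(n - 1L), ] <- points[3:n, , drop = FALSE] -
                              points[1:(n - 2L), , drop = FALSE]
  tangents <- tangents / sqrt(rowSums(tangents^2))
  structure(list(points = points, arclength = arclength,
                 tangents = tangents, interval = mean(seg)),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, length %.3f mm, mean interval %.4f mm\n",
              nrow(x$points), max(x$arclength), x$interval))
  invisible(x)
}

#' Straight centerline along a given direction
#'
#' @param length total length, mm.
#' @param n number of points.
#' @param start world start point, mm.
#' @param direction direction vector (normalized internally).
#' @return a `centerline`.
#' @export
straight_centerline <- function(length, n = 101L, start = c(0, 0, 0),
                                direction = c(0, 0, 1)) {
  direction <- direction / sqrt(sum(direction^2))
  s <- seq(0, length, length.out = n)
  centerline(outer(s, direction) + matrix(start, n, 3L, byrow = TRUE))
}

#' Helical centerline parameterized by arclength
#'
#' A helix of transverse radius `helix_radius` and rise-per-turn `pitch`
#' around an axis parallel to z through `center`. Arclength-parameterized so
#' that consecutive points are uniformly spaced along the curve.
#'
#' @param length arclength, mm.
#' @param helix_radius transverse radius, mm.
#' @param pitch rise per full turn, mm. Keep pitch and radius such that
#'   successive perpendicular planes do not intersect within the vessel
#'   radius (curvature radius well above the vessel radius).
#' @param n number of points.
#' @param center axis position in x/y and z of the first point, mm.
#' @param phase starting angle, radians.
#' @return a `centerline`.
#' @export
helical_centerline <- function(length, helix_radius = 1, pitch = 40,
                               n = 201L, center = c(0, 0, 0), phase = 0) {
  turn_len <- sqrt((2 * pi * helix_radius)^2 + pitch^2)
  omega <- 2 * pi / turn_len      # angle per unit arclength
  h <- pitch / turn_len           # axial rise per unit arclength
  s <- seq(0, length, length.out = n)
  pts <- cbind(center[1L] + helix_radius * cos(omega * s + phase),
               center[2L] + helix_radius * sin(omega * s + phase),
               center[3L] + h * s)
  centerline(pts)
}

#' Resample a centerline at a uniform arclength interval
#'
#' Positions are linearly interpolated against the original cumulative
#' arclength at `seq(0, L, by = interval)`; tangents are recomputed from the
#' resampled polyline (central differences, one-sided at the ends).
#'
#' @param c a `centerline`.
#' @param interval target arclength spacing, mm; must lie in (0, L].
#' @return a `centerline` with `floor(L / interval) + 1` points.
#' @export
resample_centerline <- function(c, interval) {
  if (!inherits(c, "centerline")) stopf("expected a centerline")
  L <- max(c$arclength)
  if (!is.finite(interval) || interval <= 0) stopf("interval must be positive")
  if (interval > L + 1e-12) stopf("interval (%g mm) exceeds centerline length (%g mm)", interval, L)
  s_new <- seq(0, by = interval, length.out = floor(L / interval + 1e-9) + 1L)
  pts <- vapply(1:3, function(j)
    stats::approx(c$arclength, c$points[, j], xout = s_new)$y,
    numeric(length(s_new)))
  centerline(pts)
}

#' Rotation-minimizing plane bases along a centerline
#'
#' Produces, for each point, two orthonormal in-plane vectors perpendicular
#' to the tangent, varying with minimal rotation from plane to plane. With
#' `points` supplied, the double-reflection method is used; with tangents
#' only, frames are transported by the minimal (Rodrigues) rotation mapping
#' each tangent onto the next.
#'
#' @param tangents n x 3 matrix of unit tangents.
#' @param points optional n x 3 matrix of the corresponding points (enables
#'   the double-reflection construction).
#' @return list of `e1` and `e2`, each n x 3 with unit rows.
#' @export
plane_basis <- function(tangents, points = NULL) {
  tangents <- matrix(as.numeric(tangents), ncol = 3L)
  n <- nrow(tangents)
  nrm <- sqrt(rowSums(tangents^2))
  if (any(nrm < 1e-12)) stopf("zero tangent vector")
  if (any(abs(nrm - 1) > 1e-6)) stopf("tangents must be unit vectors")
  e1 <- matrix(0, n, 3L); e2 <- matrix(0, n, 3L)
  ## initial normal: project the least-aligned axis onto the first plane
  t1 <- tangents[1L, ]
  ax <- diag(3L)[, which.min(abs(t1))]
  v <- ax - sum(ax * t1) * t1
  e1[1L, ] <- v / sqrt(sum(v^2))
  e2[1L, ] <- crossp(t1, e1[1L, ])
  use_dr <- !is.null(points)
  if (use_dr) points <- matrix(as.numeric(points), ncol = 3L)
  for (i in seq_len(n - 1L)) {
    ti <- tangents[i, ]; tn <- tangents[i + 1L, ]
    ri <- e1[i, ]
    if (use_dr) {
      ## double reflection (Wang et al. 2008): reflect in the chord
      ## bisector plane, then in the tangent bisector plane
      v1 <- points[i + 1L, ] - points[i, ]
      c1 <- sum(v1 * v1)
      if (c1 < 1e-24) { rL <- ri; tL <- ti } else {
        rL <- ri - (2 / c1) * sum(v1 * ri) * v1
        tL <- ti - (2 / c1) * sum(v1 * ti) * v1
      }
      v2 <- tn - tL
      c2 <- sum(v2 * v2)
      rn <- if (c2 < 1e-24) rL else rL - (2 / c2) * sum(v2 * rL) * v2
    } else {
      ## minimal rotation taking ti to tn
      axis <- crossp(ti, tn)
      sa <- sqrt(sum(axis^2))
      ca <- sum(ti * tn)
      if (sa < 1e-14) {
        rn <- if (ca > 0) ri else -ri  # parallel (or antiparallel) tangents
      } else {
        k <- axis / sa
        rn <- ri * ca + crossp(k, ri) * sa + k * sum(k * ri) * (1 - ca)
      }
    }
    ## re-orthogonalize against accumulated rounding
    rn <- rn - sum(rn * tn) * tn
    e1[i + 1L, ] <- rn / sqrt(sum(rn^2))
    e2[i + 1L, ] <- crossp(tn, e1[i + 1L, ])
  }
  list(e1 = e1, e2 = e2)
}

crossp <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Extract a cross-sectional plane from a volume
#'
#' Samples the volume by trilinear interpolation on a square in-plane grid
#' of side `fov`, centered at `point` and spanned by the orthonormal basis
#' `(e1, e2)`. Samples falling outside the volume take the `fill` value and
#' are flagged; flagged pixels are excluded from boundary searches
#' downstream.
#'
#' @param v an `hu_volume`.
#' @param point world center of the plane (a centerline point), mm.
#' @param basis list with unit vectors `e1`, `e2` orthogonal to the tangent.
#' @param fov in-plane field of view (square side), mm.
#' @param spacing in-plane sample spacing, mm. Default 0.1 mm: finer than
#'   typical CT voxels so boundary localization is not grid-limited.
#' @param s arclength of the plane along the centerline, mm (metadata).
#' @param fill value for out-of-volume samples (default -1024 HU).
#' @return object of class `cross_section`: fields `grid` (m x m HU),
#'   `oob` (logical m x m), `in_plane_spacing`, `center_index` (1-based row
#'   and column of the centerline point), `s`, `basis`, `point`.
#' @export
extract_cross_section <- function(v, point, basis, fov = 10, spacing = 0.1,
                                  s = NA_real_, fill = -1024) {
  if (!inherits(v, "hu_volume")) stopf("expected an hu_volume")
  if (!is.finite(fov) || fov <= 0 || !is.finite(spacing) || spacing <= 0)
    stopf("fov and spacing must be positive")
  e1 <- as.numeric(basis$e1); e2 <- as.numeric(basis$e2)
  half <- floor(fov / (2 * spacing))
  u <- seq.int(-half, half) * spacing
  m <- length(u)
  U <- matrix(u, m, m); V <- matrix(u, m, m, byrow = TRUE)
  pts <- cbind(point[1L] + U * e1[1L] + V * e2[1L],
               point[2L] + U * e1[2L] + V * e2[2L],
               point[3L] + U * e1[3L] + V * e2[3L])
  res <- interp_trilinear(v$values, v$spacing, v$origin, pts, fill = fill)
  structure(list(grid = matrix(res$values, m, m),
                 oob = matrix(res$oob, m, m),
                 in_plane_spacing = spacing,
                 center_index = c(half + 1L, half + 1L),
                 s = s, basis = list(e1 = e1, e2 = e2),
                 point = as.numeric(point)),
            class = "cross_section")
}

#' Build a synthetic cross-section directly from a function of (x, y)
#'
#' Convenience for tests and examples: evaluates `f(x, y)` (in-plane mm,
#' centered at the plane center) on the sampling grid of
#' [extract_cross_section()].
#'
#' @param f vectorized function of in-plane coordinates (mm) returning HU.
#' @param fov,spacing as in [extract_cross_section()].
#' @return a `cross_section`.
#' @export
synthetic_cross_section <- function(f, fov = 10, spacing = 0.1) {
  half <- floor(fov / (2 * spacing))
  u <- seq.int(-half, half) * spacing
  m <- length(u)
  U <- matrix(u, m, m); V <- matrix(u, m, m, byrow = TRUE)
  structure(list(grid = matrix(f(U, V), m, m),
                 oob = matrix(FALSE, m, m),
                 in_plane_spacing = spacing,
                 center_index = c(half + 1L, half + 1L),
                 s = NA_real_,
                 basis = list(e1 = c(1, 0, 0), e2 = c(0, 1, 0)),
                 point = c(0, 0, 0)),
            class = "cross_section")
}
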