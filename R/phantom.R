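## Digital vessel phantom with analytic ground truth.
##
## The phantom emulates a contrast-enhanced coronary target segment: a
## bright lumen tube inside a soft-plaque wall, optionally with a dense
## calcium arc and an adjacent high-attenuation chamber, rasterized into a
## CT-like HU grid with partial-volume blur and additive noise. Ground
## truth (areas, burden, volumes) comes from the unblurred geometry, so it
## plays the role of a fine-interval pullback reference (the role IVUS
## plays for clinical CT) with exactly known values.

## preserve the caller's RNG state while using a local seed
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Specify a digital vessel phantom
#'
#' Defaults describe a realistic proximal coronary target segment: a 25 mm
#' segment with 4 mm lumen diameter and 6 mm outer vessel diameter, a 50%
#' focal stenosis over 8 mm at mid-segment (plaque burden rises from ~0.56
#' at baseline to ~0.89 at the throat, so the burden profile crosses the
#' 0.6 stenotic-subgroup threshold), contrast-enhanced lumen at 400 HU,
#' soft plaque at 60 HU, epicardial-fat-like background at -50 HU, 0.25 mm
#' partial-volume blur and 20 HU noise on isotropic 0.4 mm voxels.
#'
#' @param segment_length segment length, mm.
#' @param base_lumen_radius lumen radius away from the stenosis, mm.
#' @param base_vessel_radius outer vessel radius (constant along s), mm.
#' @param stenosis_center arclength of the stenosis throat, mm.
#' @param stenosis_length full length of the stenotic taper, mm.
#' @param stenosis_severity fractional lumen-radius reduction at the
#'   throat, in [0, 1).
#' @param lumen_hu,plaque_hu,calcium_hu,background_hu tissue attenuations, HU.
#' @param calcium_arc optional `c(start_angle, end_angle, s_start, s_end)`
#'   (radians, radians, mm, mm): the angular sector of the plaque annulus
#'   replaced by calcium between the two arclengths. Angles are measured in
#'   the rotation-minimizing in-plane frame.
#' @param chamber optional `c(offset_x, offset_y, radius, hu)`: an adjacent
#'   high-attenuation cylinder (e.g. a cardiac chamber) parallel to the
#'   vessel at the given transverse offset (mm, mm, mm, HU).
#' @param blur_sigma Gaussian blur, mm (partial-volume surrogate).
#' @param noise_sd additive Gaussian noise, HU (applied after blur).
#' @param voxel_spacing voxel size, mm (scalar or length 3).
#' @param seed integer seed for the noise field.
#' @param centerline_type `"straight"` or `"helical"`.
#' @param helix_radius,helix_pitch helix transverse radius and rise per
#'   turn, mm (used when `centerline_type = "helical"`; keep the curvature
#'   radius well above `base_vessel_radius` so planes do not intersect).
#' @param transverse_margin,end_margin clearance between vessel and grid
#'   edge, mm.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(segment_length = 25,
                         base_lumen_radius = 2,
                         base_vessel_radius = 3,
                         stenosis_center = 12.5,
                         stenosis_length = 8,
                         stenosis_severity = 0.5,
                         lumen_hu = 400, plaque_hu = 60,
                         calcium_hu = 800, background_hu = -50,
                         calcium_arc = NULL, chamber = NULL,
                         blur_sigma = 0.25, noise_sd = 20,
                         voxel_spacing = 0.4, seed = 20260920L,
                         centerline_type = c("straight", "helical"),
                         helix_radius = 1, helix_pitch = 60,
                         transverse_margin = 3, end_margin = 2) {
  centerline_type <- match.arg(centerline_type)
  spec <- list(segment_length = segment_length,
               base_lumen_radius = base_lumen_radius,
               base_vessel_radius = base_vessel_radius,
               stenosis_center = stenosis_center,
               stenosis_length = stenosis_length,
               stenosis_severity = stenosis_severity,
               lumen_hu = lumen_hu, plaque_hu = plaque_hu,
               calcium_hu = calcium_hu, background_hu = background_hu,
               calcium_arc = calcium_arc, chamber = chamber,
               blur_sigma = blur_sigma, noise_sd = noise_sd,
               voxel_spacing = rep_len(as.numeric(voxel_spacing), 3L),
               seed = as.integer(seed),
               centerline_type = centerline_type,
               helix_radius = helix_radius, helix_pitch = helix_pitch,
               transverse_margin = transverse_margin,
               end_margin = end_margin)
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(s) {
  if (!is.finite(s$segment_length) || s$segment_length <= 0)
    stopf("segment_length must be positive")
  if (!(s$base_lumen_radius > 0 && s$base_lumen_radius <= s$base_vessel_radius))
    stopf("need 0 < base_lumen_radius <= base_vessel_radius")
  if (!(s$stenosis_severity >= 0 && s$stenosis_severity < 1))
    stopf("stenosis_severity must lie in [0, 1)")
  if (s$stenosis_length <= 0) stopf("stenosis_length must be positive")
  if (any(s$voxel_spacing <= 0)) stopf("voxel_spacing must be positive on every axis")
  if (s$blur_sigma < 0) stopf("blur_sigma must be >= 0")
  if (s$noise_sd < 0) stopf("noise_sd must be >= 0")
  if (!is.null(s$calcium_arc) && length(s$calcium_arc) != 4L)
    stopf("calcium_arc must be c(start_angle, end_angle, s_start, s_end)")
  if (!is.null(s$chamber) && length(s$chamber) != 4L)
    stopf("chamber must be c(offset_x, offset_y, radius, hu)")
  if (s$transverse_margin < 0 || s$end_margin < 0)
    stopf("margins must be >= 0 (vessel would extend beyond the grid)")
  invisible(s)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("<phantom_spec> L=%g mm, lumen r=%g mm, vessel r=%g mm, ",
                     "stenosis %g%% @ %g mm (len %g mm), %s centerline\n"),
              x$segment_length, x$base_lumen_radius, x$base_vessel_radius,
              100 * x$stenosis_severity, x$stenosis_center,
              x$stenosis_length, x$centerline_type))
  invisible(x)
}

## smooth cosine bump: 1 at the stenosis center, 0 outside stenosis_length
stenosis_weight <- function(spec, s) {
  half <- spec$stenosis_length / 2
  u <- (s - spec$stenosis_center) / half
  w <- ifelse(abs(u) < 1, 0.5 * (1 + cos(pi * u)), 0)
  w
}

#' Lumen radius at arclength s
#'
#' `base_lumen_radius * (1 - severity * w(s))` where `w` is a smooth cosine
#' bump equal to 1 at the stenosis center and 0 outside the stenosis. The
#' outer vessel radius is unchanged, so plaque thickens at the stenosis.
#'
#' @param spec a `phantom_spec`.
#' @param s arclength, mm (vectorized); must lie in `[0, segment_length]`.
#' @return lumen radius, mm.
#' @export
stenosis_radius <- function(spec, s) {
  if (any(s < 0 | s > spec$segment_length))
    stopf("arclength out of range [0, %g]", spec$segment_length)
  spec$base_lumen_radius * (1 - spec$stenosis_severity * stenosis_weight(spec, s))
}

## integral of pi * r_l(s)^2 and annulus complement, closed form
lumen_volume_closed_form <- function(spec) {
  ## valid when the stenosis taper lies fully inside the segment
  r0 <- spec$base_lumen_radius; sev <- spec$stenosis_severity
  Ls <- spec$stenosis_length; L <- spec$segment_length
  pi * r0^2 * (L - sev * Ls + sev^2 * 3 * Ls / 8)
}

#' Analytic ground truth of a phantom
#'
#' Lumen/vessel radii as functions of arclength plus segment volumes.
#' Volumes are integrals of the analytic area profile (composite Simpson at
#' 0.001 mm), independent of rasterization, blur and noise.
#'
#' @param spec a `phantom_spec`.
#' @return object of class `vessel_truth` with fields `spec`,
#'   `lumen_radius(s)`, `vessel_radius(s)`, `lumen_volume`,
#'   `vessel_volume`, `plaque_volume` (mm^3).
#' @export
phantom_truth <- function(spec) {
  lr <- function(s) stenosis_radius(spec, s)
  vr <- function(s) rep_len(spec$base_vessel_radius, length(s))
  s_fine <- seq(0, spec$segment_length, by = 0.001)
  la <- pi * lr(s_fine)^2
  va <- pi * vr(s_fine)^2
  lv <- simpson_integral(la, 0.001)
  vv <- simpson_integral(va, 0.001)
  structure(list(spec = spec, lumen_radius = lr, vessel_radius = vr,
                 lumen_volume = lv, vessel_volume = vv,
                 plaque_volume = vv - lv),
            class = "vessel_truth")
}

#' Evaluate ground-truth areas and burden at given arclengths
#'
#' @param truth a `vessel_truth`.
#' @param s arclengths, mm.
#' @return data.frame with `s_mm`, `lumen_area_mm2`, `vessel_area_mm2`,
#'   `plaque_area_mm2`, `plaque_burden`.
#' @export
truth_areas <- function(truth, s) {
  la <- pi * truth$lumen_radius(s)^2
  va <- pi * truth$vessel_radius(s)^2
  data.frame(s_mm = s, lumen_area_mm2 = la, vessel_area_mm2 = va,
             plaque_area_mm2 = va - la, plaque_burden = (va - la) / va)
}

#' Reference area profile at a fine interval
#'
#' Samples the analytic truth at the requested interval, emulating a
#' fine-interval pullback reference (endpoints inclusive:
#' `floor(L / interval) + 1` planes).
#'
#' @param truth a `vessel_truth`.
#' @param interval sampling interval, mm; must lie in (0, segment_length].
#' @return an [area_profile()].
#' @export
reference_area_profile <- function(truth, interval) {
  L <- truth$spec$segment_length
  if (!is.finite(interval) || interval <= 0) stopf("interval must be positive")
  if (interval > L) stopf("interval (%g mm) exceeds segment length (%g mm)", interval, L)
  s <- seq(0, by = interval, length.out = floor(L / interval + 1e-9) + 1L)
  ta <- truth_areas(truth, s)
  area_profile(positions = ta$s_mm, lumen_area = ta$lumen_area_mm2,
               vessel_area = ta$vessel_area_mm2, interval = interval)
}

## composite Simpson; trapezoid on a trailing odd panel; trapezoid for n = 2
simpson_integral <- function(y, h) {
  n <- length(y)
  if (n < 2L) stopf("need at least 2 samples to integrate")
  if (n == 2L) return(h * (y[1L] + y[2L]) / 2)
  m <- if (n %% 2L == 1L) n else n - 1L
  w <- rep(c(2, 4), length.out = m)
  w[1L] <- 1; w[m] <- 1
  out <- h / 3 * sum(w * y[1:m])
  if (m < n) out <- out + h * (y[n - 1L] + y[n]) / 2
  out
}

#' Generate a vessel phantom volume with ground truth
#'
#' Rasterizes the concentric lumen/plaque tubes (plus optional calcium arc
#' and chamber) into an HU grid with 4x-per-axis supersampled anti-aliasing,
#' applies Gaussian blur (partial-volume surrogate) and then additive
#' Gaussian noise with the spec's seed. The returned centerline is sampled
#' at 0.1 mm; ground truth is computed analytically from the unblurred
#' geometry.
#'
#' @param spec a `phantom_spec`.
#' @return list with `volume` (an `hu_volume`), `centerline` (a
#'   `centerline`), `truth` (a `vessel_truth`).
#' @export
make_vessel_phantom <- function(spec) {
  validate_phantom_spec(spec)
  sp <- spec$voxel_spacing
  reach <- spec$base_vessel_radius +
    if (spec$centerline_type == "helical") spec$helix_radius else 0
  if (!is.null(spec$chamber))
    reach <- max(reach, sqrt(sum(spec$chamber[1:2]^2)) + spec$chamber[3L])
  ext_t <- 2 * (reach + spec$transverse_margin)
  ext_z <- spec$segment_length + 2 * spec$end_margin
  nx <- ceiling(ext_t / sp[1L]); ny <- ceiling(ext_t / sp[2L])
  nz <- ceiling(ext_z / sp[3L])
  if (nx < 2L || ny < 2L || nz < 2L) stopf("phantom grid has zero size")
  cx <- nx * sp[1L] / 2; cy <- ny * sp[2L] / 2; z0 <- spec$end_margin
  if (reach > min(cx, cy)) stopf("vessel extends beyond the grid")

  f <- 4L  # supersampling factor per axis (anti-aliased rasterization)
  fs <- sp / f
  xs <- (seq_len(nx * f) - 0.5) * fs[1L]
  ys <- (seq_len(ny * f) - 0.5) * fs[2L]
  zs <- (seq_len(nz * f) - 0.5) * fs[3L]
  nfx <- nx * f; nfy <- ny * f; nfz <- nz * f
  X <- rep(xs, times = nfy * nfz)
  Y <- rep(rep(ys, each = nfx), times = nfz)
  Z <- rep(zs, each = nfx * nfy)

  ## map each sample to (s, r, theta) relative to the centerline
  if (spec$centerline_type == "straight") {
    s_raw <- Z - z0
    u <- X - cx
    v <- Y - cy
    cl <- straight_centerline(spec$segment_length,
                              n = round(spec$segment_length / 0.1) + 1L,
                              start = c(cx, cy, z0))
  } else {
    P <- cbind(X, Y, Z)
    turn_len <- sqrt((2 * pi * spec$helix_radius)^2 + spec$helix_pitch^2)
    omega <- 2 * pi / turn_len
    h <- spec$helix_pitch / turn_len
    axc <- c(cx - spec$helix_radius, cy)  # first point at angle 0
    cpt <- function(s) cbind(axc[1L] + spec$helix_radius * cos(omega * s),
                             axc[2L] + spec$helix_radius * sin(omega * s),
                             z0 + h * s)
    ctan <- function(s) cbind(-spec$helix_radius * omega * sin(omega * s),
                              spec$helix_radius * omega * cos(omega * s),
                              rep_len(h, length(s)))
    ## nearest-point projection: s <- s + (p - c(s)) . t(s), |c'| = 1
    s_raw <- (P[, 3L] - z0) / h
    for (it in 1:6) {
      cc <- cpt(s_raw); tt <- ctan(s_raw)
      s_raw <- s_raw + rowSums((P - cc) * tt)
    }
    cl <- helical_centerline(spec$segment_length,
                             helix_radius = spec$helix_radius,
                             pitch = spec$helix_pitch,
                             n = round(spec$segment_length / 0.1) + 1L,
                             center = c(axc, z0))
    ## in-plane coordinates in the rotation-minimizing frame, interpolated
    ## from a fine frame table
    s_tab <- cl$arclength
    fb <- plane_basis(cl$tangents, cl$points)
    s_cl <- pmin(pmax(s_raw, 0), spec$segment_length)
    e1i <- vapply(1:3, function(j) stats::approx(s_tab, fb$e1[, j], xout = s_cl)$y,
                  numeric(length(s_cl)))
    e2i <- vapply(1:3, function(j) stats::approx(s_tab, fb$e2[, j], xout = s_cl)$y,
                  numeric(length(s_cl)))
    cc <- cpt(s_raw)
    dp <- P - cc
    u <- rowSums(dp * e1i)
    v <- rowSums(dp * e2i)
  }
  r <- sqrt(u^2 + v^2)
  theta <- atan2(v, u) %% (2 * pi)
  ## radius profile continues past the segment ends so end planes are clean
  s_cl <- pmin(pmax(s_raw, 0), spec$segment_length)
  r_l <- stenosis_radius(spec, s_cl)
  r_v <- spec$base_vessel_radius

  hu <- rep(spec$background_hu, length(X))
  if (!is.null(spec$chamber)) {
    ch <- spec$chamber
    in_ch <- (X - (cx + ch[1L]))^2 + (Y - (cy + ch[2L]))^2 <= ch[3L]^2
    hu[in_ch] <- ch[4L]
  }
  in_vessel <- r <= r_v
  hu[in_vessel] <- spec$plaque_hu
  if (!is.null(spec$calcium_arc)) {
    ca <- spec$calcium_arc
    a1 <- ca[1L] %% (2 * pi); a2 <- ca[2L] %% (2 * pi)
    in_arc <- if (a1 <= a2) theta >= a1 & theta <= a2 else theta >= a1 | theta <= a2
    in_ca <- in_vessel & r > r_l & in_arc & s_raw >= ca[3L] & s_raw <= ca[4L]
    hu[in_ca] <- spec$calcium_hu
  }
  hu[r <= r_l] <- spec$lumen_hu

  dim(hu) <- c(nfx, nfy, nfz)
  vox <- downsample_mean_3d(hu, f)
  if (spec$blur_sigma > 0)
    vox <- blur_gaussian_3d(vox, spec$blur_sigma / sp)
  if (spec$noise_sd > 0)
    vox <- vox + with_seed(spec$seed,
                           array(stats::rnorm(length(vox), 0, spec$noise_sd),
                                 dim(vox)))
  vol <- hu_volume(vox, spacing = sp, origin = sp / 2)
  list(volume = vol, centerline = cl, truth = phantom_truth(spec))
}
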