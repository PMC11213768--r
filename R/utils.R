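## Shared numerical helpers: interpolation and Gaussian filtering.
## Conventions used throughout the package:
##   * world coordinates are in mm;
##   * voxel/pixel indices are 0-based in the maths (1-based only at R
##     subscript sites);
##   * the world position of voxel (i, j, k) is origin + c(i, j, k) * spacing.

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Trilinear interpolation of a 3D grid at world points
#'
#' Samples a scalar grid by trilinear interpolation. Points outside the
#' convex hull of voxel centers receive `fill` and are flagged. Exact for
#' affine fields and reproduces voxel values at voxel centers.
#'
#' @param values 3D numeric array.
#' @param spacing numeric length-3, mm per voxel along each axis.
#' @param origin numeric length-3, world position (mm) of voxel (0,0,0).
#' @param pts n x 3 matrix of world points (mm).
#' @param fill value assigned to out-of-grid points (default -1024, air).
#' @return list with `values` (length n) and `oob` (logical length n).
#' @keywords internal
interp_trilinear <- function(values, spacing, origin, pts, fill = -1024) {
  d <- dim(values)
  if (length(d) != 3L) stopf("trilinear interpolation requires a 3D array")
  pts <- matrix(as.numeric(pts), ncol = 3L)
  ix <- (pts[, 1L] - origin[1L]) / spacing[1L]
  iy <- (pts[, 2L] - origin[2L]) / spacing[2L]
  iz <- (pts[, 3L] - origin[3L]) / spacing[3L]
  eps <- 1e-9
  oob <- ix < -eps | ix > d[1L] - 1 + eps |
         iy < -eps | iy > d[2L] - 1 + eps |
         iz < -eps | iz > d[3L] - 1 + eps
  i0 <- pmin(pmax(floor(ix), 0), d[1L] - 2L)
  j0 <- pmin(pmax(floor(iy), 0), d[2L] - 2L)
  k0 <- pmin(pmax(floor(iz), 0), d[3L] - 2L)
  fx <- ix - i0; fy <- iy - j0; fz <- iz - k0
  ## linear (1-based) index into the array for 0-based voxel (i,j,k)
  lin <- function(i, j, k) 1 + i + d[1L] * (j + d[2L] * k)
  v000 <- values[lin(i0,     j0,     k0)]
  v100 <- values[lin(i0 + 1, j0,     k0)]
  v010 <- values[lin(i0,     j0 + 1, k0)]
  v110 <- values[lin(i0 + 1, j0 + 1, k0)]
  v001 <- values[lin(i0,     j0,     k0 + 1)]
  v101 <- values[lin(i0 + 1, j0,     k0 + 1)]
  v011 <- values[lin(i0,     j0 + 1, k0 + 1)]
  v111 <- values[lin(i0 + 1, j0 + 1, k0 + 1)]
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out <- c0 * (1 - fz) + c1 * fz
  out[oob] <- fill
  list(values = out, oob = oob)
}

#' Bilinear interpolation of a 2D grid at continuous pixel coordinates
#'
#' @param grid 2D numeric matrix.
#' @param px,py 0-based continuous pixel coordinates (rows, columns).
#' @return list with `values` and logical `oob`.
#' @keywords internal
interp_bilinear <- function(grid, px, py, fill = NA_real_) {
  d <- dim(grid)
  eps <- 1e-9
  oob <- px < -eps | px > d[1L] - 1 + eps | py < -eps | py > d[2L] - 1 + eps
  i0 <- pmin(pmax(floor(px), 0), d[1L] - 2L)
  j0 <- pmin(pmax(floor(py), 0), d[2L] - 2L)
  fx <- px - i0; fy <- py - j0
  lin <- function(i, j) 1 + i + d[1L] * j
  v00 <- grid[lin(i0, j0)]
  v10 <- grid[lin(i0 + 1, j0)]
  v01 <- grid[lin(i0, j0 + 1)]
  v11 <- grid[lin(i0 + 1, j0 + 1)]
  out <- (v00 * (1 - fx) + v10 * fx) * (1 - fy) +
         (v01 * (1 - fx) + v11 * fx) * fy
  out[oob] <- fill
  list(values = out, oob = oob)
}

## Normalized discrete Gaussian kernel; half-width 4 sigma (in samples).
gaussian_kernel <- function(sigma_samples) {
  if (sigma_samples <= 0) return(1)
  k <- max(1L, ceiling(4 * sigma_samples))
  t <- seq.int(-k, k)
  w <- exp(-0.5 * (t / sigma_samples)^2)
  w / sum(w)
}

#' 1D Gaussian smoothing with edge replication
#' @keywords internal
smooth_gaussian_1d <- function(x, sigma_samples) {
  w <- gaussian_kernel(sigma_samples)
  if (length(w) == 1L) return(x)
  k <- (length(w) - 1L) / 2L
  n <- length(x)
  xp <- c(rep(x[1L], k), x, rep(x[n], k))
  out <- numeric(n)
  for (t in seq_along(w)) out <- out + w[t] * xp[seq.int(t, t + n - 1L)]
  out
}

## Separable 3D Gaussian blur (sigma per axis, in voxels), replicate edges.
blur_gaussian_3d <- function(a, sigma_vox) {
  d <- dim(a)
  for (ax in 1:3) {
    w <- gaussian_kernel(sigma_vox[ax])
    if (length(w) == 1L) next
    k <- (length(w) - 1L) / 2L
    n <- d[ax]
    ## replicate-pad along axis `ax`, then weighted sum of shifted slabs
    idx_pad <- c(rep(1L, k), seq_len(n), rep(n, k))
    ap <- switch(ax,
                 a[idx_pad, , , drop = FALSE],
                 a[, idx_pad, , drop = FALSE],
                 a[, , idx_pad, drop = FALSE])
    out <- array(0, d)
    for (t in seq_along(w)) {
      sl <- seq.int(t, t + n - 1L)
      out <- out + w[t] * switch(ax,
                                 ap[sl, , , drop = FALSE],
                                 ap[, sl, , drop = FALSE],
                                 ap[, , sl, drop = FALSE])
    }
    a <- out
  }
  a
}

## mean-pool an array by integer factor per axis (used by the phantom
## rasterizer to average supersampled values down to the voxel grid)
downsample_mean_3d <- function(a, f) {
  d <- dim(a)
  stopifnot(all(d %% f == 0))
  dn <- d %/% f
  dim(a) <- c(f, dn[1L], f, dn[2L], f, dn[3L])
  a <- aperm(a, c(1L, 3L, 5L, 2L, 4L, 6L))
  dim(a) <- c(f^3, prod(dn))
  out <- colMeans(a)
  dim(out) <- dn
  out
}

## circular median filter of odd window w applied to a numeric vector
median_filter_circular <- function(x, w = 3L) {
  n <- length(x)
  if (n < w) return(x)
  h <- (w - 1L) %/% 2L
  xp <- c(x[(n - h + 1L):n], x, x[1:h])
  vapply(seq_len(n), function(i) stats::median(xp[i:(i + w - 1L)]), numeric(1))
}
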