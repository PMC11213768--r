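## File I/O and the reproducible end-to-end pipeline.
##
## Formats: NIfTI for volumes (spacing in the header, mm); CSV with
## documented headers for centerlines (s_mm, x_mm, y_mm, z_mm), area
## profiles (s_mm, lumen_area_mm2, vessel_area_mm2, plaque_area_mm2,
## plaque_burden) and contours (s_mm, angle_rad, lumen_r_mm, vessel_r_mm,
## flag); Wavefront OBJ for the stacked 3D model; JSON for configs,
## reports and the run manifest.

#' Read an attenuation volume from NIfTI
#'
#' The index-to-world affine must be axis-aligned (diagonal up to sign):
#' anisotropic spacing is fine, sheared or rotated affines are rejected
#' because the volume container models world coordinates as
#' `origin + index * spacing`.
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @return an [hu_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stopf("volume file not found: %s", path)
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  M <- aff[1:3, 1:3]
  off <- M; diag(off) <- 0
  if (max(abs(off)) > 1e-6 * max(abs(M))) {
    MtM <- crossprod(M)
    d <- MtM; diag(d) <- 0
    if (max(abs(d)) <= 1e-6 * max(abs(MtM)))
      stopf("rotated (non-axis-aligned) affine not supported: %s", path)
    stopf("sheared affine rejected: %s", path)
  }
  spacing <- abs(diag(M))
  vals <- array(as.numeric(img), dim = dim(img))
  origin <- aff[1:3, 4L]
  ## fold negative axes into a canonical +x/+y/+z orientation
  for (ax in 1:3) {
    if (diag(M)[ax] < 0) {
      n <- dim(vals)[ax]
      idx <- rev(seq_len(n))
      vals <- switch(ax, vals[idx, , , drop = FALSE],
                     vals[, idx, , drop = FALSE],
                     vals[, , idx, drop = FALSE])
      origin[ax] <- origin[ax] + diag(M)[ax] * (n - 1)
    }
  }
  hu_volume(vals, spacing = spacing, origin = origin)
}

#' Write an attenuation volume to NIfTI
#'
#' @param v an `hu_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_volume <- function(v, path) {
  aff <- diag(4)
  diag(aff)[1:3] <- v$spacing
  aff[1:3, 4L] <- v$origin
  img <- RNifti::asNifti(v$values)
  RNifti::pixdim(img) <- v$spacing
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Write / read a centerline as CSV (columns s_mm, x_mm, y_mm, z_mm)
#' @param c a `centerline`.
#' @param path CSV path.
#' @return the path (write) or a `centerline` (read).
#' @export
write_centerline_csv <- function(c, path) {
  df <- data.frame(s_mm = c$arclength, x_mm = c$points[, 1L],
                   y_mm = c$points[, 2L], z_mm = c$points[, 3L])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_centerline_csv
#' @export
read_centerline_csv <- function(path) {
  if (!file.exists(path)) stopf("centerline file not found: %s", path)
  df <- utils::read.csv(path)
  need <- c("s_mm", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    stopf("centerline CSV must have header columns %s", paste(need, collapse = ", "))
  centerline(as.matrix(df[, c("x_mm", "y_mm", "z_mm")]))
}

#' Write / read an area profile as CSV
#' @param profile an `area_profile`.
#' @param path CSV path.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  if (!file.exists(path)) stopf("profile file not found: %s", path)
  df <- utils::read.csv(path)
  need <- c("s_mm", "lumen_area_mm2", "vessel_area_mm2")
  if (!all(need %in% names(df)))
    stopf("profile CSV must have header columns %s", paste(need, collapse = ", "))
  d <- diff(df$s_mm)
  iv <- if (length(d) > 0L && max(abs(d - d[1L])) < 1e-6) d[1L] else NA_real_
  area_profile(df$s_mm, df$lumen_area_mm2, df$vessel_area_mm2, interval = iv)
}

#' Write per-plane contours as CSV (s_mm, angle_rad, lumen_r_mm,
#' vessel_r_mm, flag)
#' @param contours list of `contour_pair` (from [segment_vessel()]).
#' @param path CSV path.
#' @export
write_contours_csv <- function(contours, path) {
  rows <- lapply(contours, function(ct)
    data.frame(s_mm = ct$s, angle_rad = ct$angles,
               lumen_r_mm = ct$lumen_radii, vessel_r_mm = ct$vessel_radii,
               flag = ct$flags))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Export a stacked contour model as Wavefront OBJ
#'
#' Lumen and vessel surfaces are written as triangulated tubes connecting
#' consecutive contour rings.
#'
#' @param model a `stacked_model` from [segment_vessel()].
#' @param path OBJ path.
#' @export
write_obj <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# stacked vessel contour model (mm)", con)
  n_off <- 0L
  for (surface in c("lumen", "vessel")) {
    writeLines(sprintf("o %s", surface), con)
    rings <- lapply(model$rings, `[[`, surface)
    nv <- nrow(rings[[1L]])
    for (ring in rings)
      writeLines(sprintf("v %.6f %.6f %.6f", ring[, 1L], ring[, 2L], ring[, 3L]), con)
    for (j in seq_len(length(rings) - 1L)) {
      a <- n_off + (j - 1L) * nv + seq_len(nv)
      b <- a %% nv + (j - 1L) * nv + n_off + 1L  # next vertex on same ring
      c2 <- a + nv; d2 <- b + nv
      writeLines(sprintf("f %d %d %d", a, b, d2), con)
      writeLines(sprintf("f %d %d %d", a, d2, c2), con)
    }
    n_off <- n_off + length(rings) * nv
  }
  invisible(path)
}

#' Write an agreement report as JSON
#' @param report a `latm_report` (or any list).
#' @param path JSON path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Write / read a phantom spec as JSON
#' @param spec a `phantom_spec`.
#' @param path JSON path.
#' @export
write_phantom_json <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_phantom_json
#' @export
read_phantom_json <- function(path) {
  if (!file.exists(path)) stopf("phantom config not found: %s", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$calcium_arc <- if (length(cfg$calcium_arc)) unlist(cfg$calcium_arc) else NULL
  cfg$chamber <- if (length(cfg$chamber)) unlist(cfg$chamber) else NULL
  do.call(phantom_spec, cfg[setdiff(names(cfg), character(0))])
}

config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}

#' Run the full phantom-to-report pipeline
#'
#' Generates (or loads) a vessel phantom, segments it along its centerline
#' with the location-adaptive threshold method, quantifies areas and
#' volumes, compares the result against the fine-interval analytic
#' reference, and writes all artifacts plus a manifest recording the
#' configuration hash and seed. Identical configuration and seed produce
#' byte-identical outputs.
#'
#' @param spec a `phantom_spec` (the seed inside it drives all randomness).
#' @param out_dir output directory (created if missing).
#' @param calibration_hu calibration attenuation, HU; defaults to the
#'   phantom's lumen attenuation (an aorta-like blood-pool reference).
#' @param interval plane spacing, mm.
#' @param reference_interval reference profile interval, mm (fine,
#'   pullback-like).
#' @param cfg optional `latm_config` (built from `calibration_hu` if NULL).
#' @param burden_threshold stenotic-subgroup threshold.
#' @return list with `profile`, `reference`, `report`, `truth`, `failed`,
#'   and the paths of the written artifacts (`paths`).
#' @export
run_pipeline <- function(spec, out_dir,
                         calibration_hu = spec$lumen_hu,
                         interval = 0.25, reference_interval = 0.001,
                         cfg = NULL, burden_threshold = 0.6) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.null(cfg)) cfg <- latm_config(calibration_hu = calibration_hu)
  ph <- make_vessel_phantom(spec)
  seg <- segment_vessel(ph$volume, ph$centerline, cfg, interval = interval)
  reference <- reference_area_profile(ph$truth, reference_interval)
  report <- evaluate_platform(seg$profile, reference,
                              burden_threshold = burden_threshold)
  volumes <- list(
    lumen_volume_mm3 = volume_sum(seg$profile, "lumen"),
    plaque_volume_mm3 = volume_sum(seg$profile, "plaque"),
    reference_lumen_volume_mm3 = ph$truth$lumen_volume,
    reference_plaque_volume_mm3 = ph$truth$plaque_volume,
    n_planes = nrow(seg$profile), n_failed_planes = nrow(seg$failed))

  paths <- list(volume = file.path(out_dir, "phantom.nii.gz"),
                centerline = file.path(out_dir, "centerline.csv"),
                contours = file.path(out_dir, "contours.csv"),
                profile = file.path(out_dir, "area_profile.csv"),
                reference = file.path(out_dir, "reference_profile.csv"),
                model = file.path(out_dir, "model.obj"),
                volumes = file.path(out_dir, "volumes.json"),
                report = file.path(out_dir, "report.json"),
                manifest = file.path(out_dir, "manifest.json"))
  write_volume(ph$volume, paths$volume)
  write_centerline_csv(ph$centerline, paths$centerline)
  write_contours_csv(seg$contours, paths$contours)
  write_profile_csv(seg$profile, paths$profile)
  write_profile_csv(reference, paths$reference)
  write_obj(seg$model, paths$model)
  jsonlite::write_json(volumes, paths$volumes, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  write_report_json(report, paths$report)
  manifest <- list(package = "latmseg",
                   version = as.character(utils::packageVersion("latmseg")),
                   seed = spec$seed,
                   config_hash = config_hash(list(spec = unclass(spec),
                                                  latm = unclass(cfg),
                                                  interval = interval,
                                                  reference_interval = reference_interval,
                                                  burden_threshold = burden_threshold)),
                   interval_mm = interval,
                   calibration_hu = cfg$calibration_hu,
                   n_failed_planes = nrow(seg$failed),
                   failed_plane_s_mm = seg$failed$s_mm)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  list(profile = seg$profile, reference = reference, report = report,
       truth = ph$truth, failed = seg$failed, volumes = volumes,
       paths = paths)
}
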