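## Serialization: multi-page TIFF for image stacks (32-bit float), YAML
## sidecars for acquisition/calibration metadata, CSV for tabular outputs.

#' Write a PSF stack as multi-page TIFF plus YAML sidecar
#'
#' @param stack A [psf_stack()].
#' @param path TIFF path; the sidecar is written next to it as
#'   `<path>.yaml`.
#' @param config Optional [optical_config()] recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_psf_stack <- function(stack, path, config = NULL) {
  imgs <- lapply(seq_along(stack$z_nm), function(i) {
    im <- stack$images[, , i]
    im / max(im, 1e-12)
  })
  tiff::writeTIFF(imgs, path, bits.per.sample = 32, reduce = FALSE)
  meta <- list(kind = stack$kind, pixel_nm = stack$pixel_nm,
               z_nm = as.numeric(stack$z_nm),
               scale = vapply(seq_along(stack$z_nm), function(i)
                 max(stack$images[, , i]), numeric(1)))
  if (!is.null(config))
    meta$config <- config[c("numerical_aperture", "magnification",
                            "emission_wavelength", "immersion_index",
                            "focal_length_4f", "camera_pixel_pitch")]
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a PSF stack written by [write_psf_stack()]
#'
#' @param path TIFF path with adjacent `<path>.yaml` sidecar.
#' @return A `psf_stack`.
#' @export
read_psf_stack <- function(path) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  images <- array(0, c(dim(imgs[[1]]), length(imgs)))
  for (i in seq_along(imgs))
    images[, , i] <- imgs[[i]] * meta$scale[[i]]
  structure(list(images = images, z_nm = as.numeric(meta$z_nm),
                 pixel_nm = meta$pixel_nm, kind = meta$kind),
            class = "psf_stack")
}

#' Write a frame stream to disk
#'
#' Frames as 16-bit multi-page TIFF, ground truth and schedule as CSV, and
#' acquisition metadata as YAML.
#'
#' @param stream A [simulate_stream()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_frame_stream <- function(stream, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mx <- max(stream$frames, 65535)
  imgs <- lapply(seq_len(dim(stream$frames)[3]), function(f)
    stream$frames[, , f] / 65535)
  if (mx > 65535) warning("counts exceed 16-bit range; clipped on write")
  imgs <- lapply(imgs, function(m) pmin(m, 1))
  tiff::writeTIFF(imgs, file.path(dir, "frames.tif"), bits.per.sample = 16)
  utils::write.csv(stream$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  utils::write.csv(cbind(stream$schedule,
                         focal_applied_nm = stream$focal_z_nm,
                         dx_nm = stream$drift[, 1],
                         dy_nm = stream$drift[, 2],
                         dz_nm = stream$drift[, 3]),
                   file.path(dir, "schedule.csv"), row.names = FALSE)
  yaml::write_yaml(list(
    fov = stream$fov,
    photon_rate = stream$photon_rate,
    background = if (is.function(stream$background)) "per-role function"
                 else stream$background,
    seed = stream$seed,
    camera = if (is.null(stream$camera)) "noiseless"
             else unclass(stream$camera)),
    file.path(dir, "acquisition.yaml"))
  invisible(dir)
}

#' Read a frame stream written by [write_frame_stream()]
#'
#' Reconstructs a `frame_stream` sufficient for analysis (frames, schedule,
#' camera, field geometry; the ground-truth log if present). Counts were
#' clipped to the 16-bit range on write, as a real EM-CCD A/D would.
#'
#' @param dir Directory written by [write_frame_stream()].
#' @return A `frame_stream` (without masks; analysis functions that need a
#'   mask take it explicitly).
#' @export
read_frame_stream <- function(dir) {
  imgs <- tiff::readTIFF(file.path(dir, "frames.tif"), all = TRUE)
  frames <- array(0L, c(dim(imgs[[1]]), length(imgs)))
  for (i in seq_along(imgs))
    frames[, , i] <- as.integer(round(imgs[[i]] * 65535))
  sched <- utils::read.csv(file.path(dir, "schedule.csv"))
  meta <- yaml::read_yaml(file.path(dir, "acquisition.yaml"))
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path)) utils::read.csv(truth_path) else NULL
  camera <- if (is.character(meta$camera)) NULL else
    do.call(camera_model, meta$camera[c("exposure_ms", "em_gain",
                                        "quantum_efficiency", "read_noise_e",
                                        "offset", "conversion",
                                        "dark_frames")])
  structure(list(
    frames = frames,
    schedule = sched[c("frame", "slice", "role", "sheet_z_um", "focal_z_um")],
    truth = truth,
    drift = as.matrix(sched[c("dx_nm", "dy_nm", "dz_nm")]),
    focal_z_nm = sched$focal_applied_nm,
    feedback_log = NULL,
    fov = meta$fov,
    masks = NULL,
    roi_px = list(sm = 23, fiducial = 41),
    config = NULL,
    camera = camera,
    background = if (is.character(meta$background)) NULL else meta$background,
    photon_rate = meta$photon_rate,
    seed = meta$seed), class = "frame_stream")
}

#' Write / read a localization table as CSV
#'
#' The table keeps the documented header (`frame, x_nm, y_nm, z_nm,
#' photons, background, ...`) so it interoperates with common
#' single-molecule localization table tooling.
#'
#' @param locs Localization `data.frame`.
#' @param path CSV path.
#' @return `path` (write) or the table (read).
#' @export
write_localizations <- function(locs, path) {
  utils::write.csv(locs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) {
  utils::read.csv(path)
}

#' Render an illumination cross-section image
#'
#' Samples the illumination intensity on an xz grid at y = 0; useful for
#' inspecting the tilted-sheet geometry.
#'
#' @param field An [illumination_field()].
#' @param x_um,z_um Ranges `c(min, max)` in um.
#' @param step_um Grid step in um.
#' @return Matrix `[z, x]` of relative intensity with attributes `x_um`,
#'   `z_um`.
#' @export
illumination_map <- function(field, x_um = c(-20, 20), z_um = c(-5, 15),
                             step_um = 0.1) {
  xs <- seq(x_um[1], x_um[2], by = step_um)
  zs <- seq(z_um[1], z_um[2], by = step_um)
  img <- vapply(xs, function(x)
    intensity_at(field, x * 1000, 0, zs * 1000), numeric(length(zs)))
  structure(img, x_um = xs, z_um = zs)
}
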