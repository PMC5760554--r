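#' Simulate an interleaved single-molecule frame stream
#'
#' The synthetic microscope: advances blinking fluorophore states frame by
#' frame, renders every active emitter's engineered PSF at its drifted
#' position relative to the (possibly feedback-corrected) focal plane,
#' renders fiducial beads on their interleaved frames with their own mask,
#' adds background, and applies the EM-CCD noise chain. Every stochastic
#' element is driven by `seed`, so the same seed reproduces the stream
#' exactly, and a full ground-truth log is kept.
#'
#' @param phantom A [make_phantom()] emitter set (single-molecule channel).
#' @param schedule An [acquisition_schedule()].
#' @param illumination An [illumination_field()]. The sheet is offset axially
#'   per slice (`sheet_z_um` adds to the sheet center height).
#' @param masks `list(sm = , fiducial = )` of [build_mask()] masks assigned
#'   to the single-molecule and fiducial roles. The two roles are separate
#'   logical detection channels: each mask is rendered at its own design
#'   wavelength (e.g. far-red molecules, red fiducial beads).
#' @param config An [optical_config()].
#' @param camera A [camera_model()], or `NULL` for noiseless expected-photon
#'   frames (no offset, no noise).
#' @param blink A [blink_model()].
#' @param drift A [drift_model()].
#' @param fiducials `data.frame(x_nm, y_nm, z_nm, photons)` of beads rendered
#'   on fiducial frames (`photons` = expected photons per fiducial frame).
#' @param fov `list(nx, ny, pixel_nm)`: field of view in pixels and
#'   object-plane pixel size (default 94 x 94 at 160 nm, a 15 x 15 um field).
#' @param photon_rate Expected photons per second emitted by an on-state
#'   molecule at unit relative illumination intensity.
#' @param background Background photons per pixel per frame on
#'   single-molecule frames (scalar), e.g. from [background_rate()].
#' @param roi_px `list(sm = , fiducial = )` render ROI sizes in pixels.
#' @param feedback `NULL`, or `list(setpoint_nm =, measure =)` enabling live
#'   axial feedback: on each fiducial frame `measure(photon_frame,
#'   focal_z_nm)` returns the bead's apparent z in nm (use
#'   [make_feedback_tracker()] for a tracking-based measurement, or `NULL`
#'   measure for a ground-truth measurement); the focal plane is corrected by
#'   `measured - setpoint` starting with the next frame. A `NULL` setpoint is
#'   initialized to the first measurement.
#' @param seed Integer seed for full reproducibility.
#' @return A `frame_stream`: list with `frames` (`[ny, nx, n]` array of
#'   counts, or expected photons when `camera` is `NULL`), the `schedule`,
#'   `truth` (per rendered emitter: frame, id, true and drifted positions,
#'   defocus, expected photons, clipped flag), `drift` (per-frame nm),
#'   `focal_z_nm` (applied focal plane per frame), `feedback_log`, and the
#'   simulation parameters.
#' @export
simulate_stream <- function(phantom, schedule, illumination, masks,
                            config = optical_config(), camera = camera_model(),
                            blink = blink_model(), drift = drift_model("none"),
                            fiducials = NULL,
                            fov = list(nx = 94, ny = 94, pixel_nm = 160),
                            photon_rate = 6e4, background = 2,
                            roi_px = list(sm = 23, fiducial = 41),
                            feedback = NULL, seed = 1) {
  stopifnot(!is.null(masks$sm))
  if (!is.null(fiducials) && is.null(masks$fiducial))
    stop("fiducial frames scheduled but no fiducial mask assigned")
  set.seed(seed)
  n_frames <- nrow(schedule)
  dt <- if (is.null(camera)) 0.05 else camera$exposure_ms / 1000
  n_em <- nrow(phantom)
  ## blink states: 0 off, 1 on, 2 bleached
  state <- ifelse(stats::runif(n_em) < blink$initial_dark, 0L, 1L)
  drift_xyz <- realize_drift(drift, n_frames)
  frames <- array(if (is.null(camera)) 0 else 0L,
                  c(fov$ny, fov$nx, n_frames))
  cfg_sm <- config_for_mask(config, masks$sm)
  cfg_fid <- if (!is.null(masks$fiducial))
    config_for_mask(config, masks$fiducial) else config
  truth <- vector("list", n_frames)
  focal_log <- numeric(n_frames)
  fb_corr <- 0
  fb_set <- if (!is.null(feedback)) feedback$setpoint_nm else NULL
  fb_log <- NULL
  for (f in seq_len(n_frames)) {
    role <- schedule$role[f]
    focal_z <- schedule$focal_z_um[f] * 1000 + fb_corr
    focal_log[f] <- focal_z
    ## advance blink states (sm channel only)
    if (n_em > 0) {
      boost <- if (role == "reactivation") blink$reactivation_boost else 1
      p_leave_on <- 1 - exp(-(blink$k_off + blink$k_bleach) * dt)
      p_bleach_frac <- if (blink$k_off + blink$k_bleach > 0)
        blink$k_bleach / (blink$k_off + blink$k_bleach) else 0
      p_on <- 1 - exp(-blink$k_on * boost * dt)
      u <- stats::runif(n_em)
      was_on <- state == 1L
      was_off <- state == 0L
      leave <- was_on & (u < p_leave_on)
      state[leave] <- ifelse(stats::runif(sum(leave)) < p_bleach_frac, 2L, 0L)
      state[was_off & (u < p_on)] <- 1L
    }
    img <- matrix(0, fov$ny, fov$nx)
    log_rows <- NULL
    if (role == "fiducial") {
      if (!is.null(fiducials) && nrow(fiducials) > 0) {
        for (k in seq_len(nrow(fiducials))) {
          pos <- c(fiducials$x_nm[k] + drift_xyz[f, 1],
                   fiducials$y_nm[k] + drift_xyz[f, 2],
                   fiducials$z_nm[k] + drift_xyz[f, 3])
          clip <- add_emitter_image(img, masks$fiducial, cfg_fid, fov,
                                    pos[1], pos[2], pos[3] - focal_z,
                                    fiducials$photons[k], roi_px$fiducial)
          img <- clip$img
          log_rows <- rbind(log_rows, data.frame(
            frame = f, role = role, id = -k,
            x_nm = fiducials$x_nm[k], y_nm = fiducials$y_nm[k],
            z_nm = fiducials$z_nm[k],
            x_drift_nm = pos[1], y_drift_nm = pos[2],
            defocus_nm = pos[3] - focal_z,
            photons = fiducials$photons[k], clipped = clip$clipped))
        }
      }
      if (!is.null(feedback)) {
        meas_defocus <- if (is.null(feedback$measure)) {
          fiducials$z_nm[1] + drift_xyz[f, 3] - focal_z
        } else {
          ph_img <- img + background_for(background, role)
          feedback$measure(ph_img, focal_z)
        }
        ## express in a slice-independent gauge so that intentional focal
        ## steps between slices are not "corrected" away
        meas <- meas_defocus + schedule$focal_z_um[f] * 1000
        if (is.null(fb_set)) fb_set <- meas
        fb_corr <- fb_corr + (meas - fb_set)
        fb_log <- rbind(fb_log, data.frame(frame = f, measured_nm = meas,
                                           setpoint_nm = fb_set,
                                           correction_nm = fb_corr))
      }
    } else {
      active <- which(state == 1L)
      if (length(active) > 0) {
        sheet_off <- schedule$sheet_z_um[f] * 1000
        for (k in active) {
          pos <- c(phantom$x_nm[k] + drift_xyz[f, 1],
                   phantom$y_nm[k] + drift_xyz[f, 2],
                   phantom$z_nm[k] + drift_xyz[f, 3])
          inten <- intensity_at(offset_field(illumination, sheet_off),
                                pos[1], pos[2], pos[3])
          nph <- photon_rate * dt * inten
          if (nph <= 0) next
          clip <- add_emitter_image(img, masks$sm, cfg_sm, fov,
                                    pos[1], pos[2], pos[3] - focal_z,
                                    nph, roi_px$sm)
          img <- clip$img
          log_rows <- rbind(log_rows, data.frame(
            frame = f, role = role, id = k,
            x_nm = phantom$x_nm[k], y_nm = phantom$y_nm[k],
            z_nm = phantom$z_nm[k],
            x_drift_nm = pos[1], y_drift_nm = pos[2],
            defocus_nm = pos[3] - focal_z,
            photons = nph, clipped = clip$clipped))
        }
      }
    }
    img <- img + background_for(background, role)
    frames[, , f] <- if (is.null(camera)) img else
      apply_camera_noise(img, camera)
    truth[[f]] <- log_rows
  }
  truth <- do.call(rbind, truth[!vapply(truth, is.null, TRUE)])
  if (is.null(truth))
    truth <- data.frame(frame = integer(), role = character(),
                        id = integer(), x_nm = numeric(), y_nm = numeric(),
                        z_nm = numeric(), x_drift_nm = numeric(),
                        y_drift_nm = numeric(), defocus_nm = numeric(),
                        photons = numeric(), clipped = logical())
  structure(list(frames = frames, schedule = schedule, truth = truth,
                 drift = drift_xyz, focal_z_nm = focal_log,
                 feedback_log = fb_log, fov = fov, masks = masks,
                 roi_px = roi_px,
                 config = config, camera = camera, background = background,
                 photon_rate = photon_rate, seed = seed),
            class = "frame_stream")
}

background_for <- function(background, role) {
  if (is.function(background)) background(role) else background
}

## The two logical detection channels differ in emission wavelength; each
## mask records its design wavelength, and rendering must use it.
config_for_mask <- function(config, mask) {
  if (!is.null(mask$design_wavelength) &&
        mask$design_wavelength != config$emission_wavelength)
    config$emission_wavelength <- mask$design_wavelength
  config
}

## Shift the sheet center axially by the per-slice scan offset.
offset_field <- function(field, dz_nm) {
  if (field$mode == "sheet" && dz_nm != 0)
    field$sheet$center_z_um <- field$sheet$center_z_um + dz_nm / 1000
  field
}

## Render one emitter into a field image at drifted position (x, y) nm and
## defocus dz nm; returns the updated image and whether the ROI was clipped
## by the field edge (or skipped entirely).
add_emitter_image <- function(img, mask, config, fov, x_nm, y_nm,
                              defocus_nm, photons, roi_px) {
  px <- fov$pixel_nm
  cx <- (fov$nx + 1) / 2
  cy <- (fov$ny + 1) / 2
  ## nearest pixel to emitter; sub-pixel remainder rendered in the ROI
  jx <- round(x_nm / px + cx)
  jy <- round(y_nm / px + cy)
  half <- (roi_px - 1) / 2
  if (jx < 1 - half || jx > fov$nx + half || jy < 1 - half ||
        jy > fov$ny + half)
    return(list(img = img, clipped = TRUE))
  dx <- x_nm - (jx - cx) * px
  dy <- y_nm - (jy - cy) * px
  roi <- render_emitter(mask, defocus_nm, config, dx_nm = dx, dy_nm = dy,
                        roi_px = roi_px, pixel_nm = px) * photons
  ys <- (jy - half):(jy + half)
  xs <- (jx - half):(jx + half)
  keep_y <- ys >= 1 & ys <= fov$ny
  keep_x <- xs >= 1 & xs <= fov$nx
  img[ys[keep_y], xs[keep_x]] <- img[ys[keep_y], xs[keep_x]] +
    roi[keep_y, keep_x]
  list(img = img, clipped = !(all(keep_y) && all(keep_x)))
}

#' Re-render a noiseless frame from the ground-truth log
#'
#' Rebuilds the expected-photon image of one frame purely from the stream's
#' ground-truth log (drifted positions, defocus, photons), byte-identical to
#' the pre-noise image the simulator produced.
#'
#' @param stream A [simulate_stream()] result.
#' @param frame Frame index.
#' @return Matrix of expected photons per pixel.
#' @export
re_render_frame <- function(stream, frame) {
  img <- matrix(0, stream$fov$ny, stream$fov$nx)
  rows <- stream$truth[stream$truth$frame == frame, , drop = FALSE]
  role <- stream$schedule$role[frame]
  for (k in seq_len(nrow(rows))) {
    mask <- if (rows$id[k] < 0) stream$masks$fiducial else stream$masks$sm
    roi <- if (rows$id[k] < 0) stream$roi_px$fiducial else stream$roi_px$sm
    ## reproduce the simulator's ROI geometry and per-channel wavelength
    res <- add_emitter_image(img, mask, config_for_mask(stream$config, mask),
                             stream$fov,
                             rows$x_drift_nm[k], rows$y_drift_nm[k],
                             rows$defocus_nm[k], rows$photons[k], roi)
    img <- res$img
  }
  img + background_for(stream$background, role)
}

#' @export
print.frame_stream <- function(x, ...) {
  cat(sprintf(
    "<frame_stream> %d frames (%d x %d px, %.0f nm), %d slices, %s\n",
    dim(x$frames)[3], x$fov$ny, x$fov$nx, x$fov$pixel_nm,
    length(unique(x$schedule$slice)),
    if (is.null(x$camera)) "noiseless (expected photons)" else "EM-CCD counts"))
  invisible(x)
}
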