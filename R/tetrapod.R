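#' Render a bead z-scan on the pupil grid's natural sampling
#'
#' Produces the through-focus intensity stack a phase-retrieval calibration
#' consumes: full-field FFT renders of the mask PSF at each z, on the
#' natural pixel of the (unpadded) pupil grid, optionally with Poisson
#' photon noise.
#'
#' @param mask A [build_mask()] phase mask.
#' @param z_nm Vector of axial positions in nm.
#' @param config An [optical_config()].
#' @param photons_per_plane Expected photons per plane; 0 for noiseless.
#' @param seed Seed for the photon noise.
#' @return A `psf_stack` on the natural grid (each plane sums to ~1, or to
#'   the drawn photon count when noisy).
#' @export
bead_scan_stack <- function(mask, z_nm, config = optical_config(),
                            photons_per_plane = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- mask$grid$n_side
  images <- array(0, c(n, n, length(z_nm)))
  pixel_nm <- NA_real_
  for (i in seq_along(z_nm)) {
    im <- psf_at(mask, z_nm[i], config, pad = 1)
    pixel_nm <- attr(im, "pixel_nm")
    if (photons_per_plane > 0)
      im <- matrix(stats::rpois(length(im), photons_per_plane * im), n, n)
    images[, , i] <- im
  }
  structure(list(images = images, z_nm = z_nm, pixel_nm = pixel_nm,
                 kind = mask$kind), class = "psf_stack")
}

#' Retrieve the pupil phase from a bead z-stack
#'
#' Iterative phase retrieval by alternating projections across the
#' through-focus stack: each plane's model field takes the measured
#' magnitude while keeping the model phase, the defocus is unwound, the
#' per-plane pupil estimates are averaged, and the result is projected back
#' onto the unit-amplitude aperture. A mild complex-domain Gaussian
#' smoothing between iterations favors the smooth, deformable-mirror-
#' realizable phases this PSF family uses. The retrieved phase carries a
#' piston/tip/tilt gauge freedom; image-domain agreement, not pointwise
#' phase equality, is the acceptance metric, and residual tilt is removed by
#' centering the focal image.
#'
#' @param stack A [bead_scan_stack()]-style stack (z spanning at least 80%
#'   of the mask's nominal range; one dominant bead; images on the pupil
#'   grid's natural sampling).
#' @param grid The [pupil_grid()] used for the retrieval.
#' @param config An [optical_config()].
#' @param n_iter Iteration cap (default 200).
#' @param tol Relative image-domain error improvement below which iteration
#'   stops (default 1e-4).
#' @param smooth_px Gaussian smoothing sigma (pupil samples) applied to the
#'   complex pupil between iterations; 0 disables.
#' @param template_z_nm z grid for the regenerated template stack (default
#'   100 nm steps over the stack's span).
#' @param template_roi_px,template_pixel_nm Geometry of the camera-grid
#'   template stack.
#' @return A `tetrapod_calibration`: retrieved `phase` (radians), `error`
#'   history (normalized RMS, image domain), `converged`, plus the template
#'   stack fields of [tetrapod_calibration()].
#' @export
retrieve_pupil <- function(stack, grid = pupil_grid(),
                           config = optical_config(), n_iter = 200,
                           tol = 1e-4, smooth_px = 1,
                           template_z_nm = NULL, template_roi_px = 41,
                           template_pixel_nm = config$effective_pixel_nm) {
  n <- grid$n_side
  stopifnot(dim(stack$images)[1] == n, dim(stack$images)[2] == n)
  nz <- length(stack$z_nm)
  ## measured amplitudes, unshifted FFT layout, unit energy per plane
  meas <- lapply(seq_len(nz), function(i) {
    im <- pmax(stack$images[, , i], 0)
    im <- im / sum(im)
    sqrt(fftshift2(im))
  })
  defoc <- lapply(stack$z_nm, function(z)
    exp(1i * defocus_phase(grid, config, z)))
  ap <- ifelse(grid$aperture, 1, 0)
  amp_norm <- sqrt(sum(ap))       # unit-energy pupil normalization
  gk <- if (smooth_px > 0) {
    w <- 2 * ceiling(3 * smooth_px) + 1
    xs <- seq_len(w) - (w + 1) / 2
    k <- exp(-outer(xs^2, xs^2, `+`) / (2 * smooth_px^2))
    k / sum(k)
  } else NULL
  pup <- ap + 0i
  err_hist <- numeric(0)
  best <- Inf
  stale <- 0
  for (it in seq_len(n_iter)) {
    acc <- matrix(0 + 0i, n, n)
    err2 <- 0
    for (j in seq_len(nz)) {
      f <- pup * defoc[[j]]
      g <- stats::fft(f)
      ga <- Mod(g)
      scale <- sqrt(sum(ga^2))
      err2 <- err2 + sum((ga / scale - meas[[j]])^2)
      gp <- meas[[j]] * scale * exp(1i * Arg(g))
      fb <- stats::fft(gp, inverse = TRUE) / (n * n)
      acc <- acc + fb * Conj(defoc[[j]])
    }
    err_hist <- c(err_hist, sqrt(err2 / nz))
    if (!is.null(gk)) {
      acc <- filter2_fft(Re(acc), gk) + 1i * filter2_fft(Im(acc), gk)
    }
    pup <- ap * exp(1i * Arg(acc))
    if (!is.finite(best) || err_hist[it] < best * (1 - tol)) {
      best <- err_hist[it]
      stale <- 0
    } else stale <- stale + 1
    if (stale >= 10) break
  }
  converged <- best < err_hist[1] || best < 0.05
  if (!converged)
    warning(sprintf(
      "phase retrieval stagnated: image-domain error %.3f (start %.3f)",
      best, err_hist[1]))
  phase <- Arg(pup)
  phase[!grid$aperture] <- 0
  ## remove residual tip/tilt: center the focal-plane image
  cal_mask <- structure(list(kind = "tetrapod_retrieved", phase = phase,
                             range_um = NA_real_,
                             design_wavelength = config$emission_wavelength,
                             grid = grid), class = "phase_mask")
  im0 <- render_emitter(cal_mask, 0, config, roi_px = 61,
                        pixel_nm = template_pixel_nm)
  cy <- sum(row(im0) * im0) / sum(im0) - 31
  cx <- sum(col(im0) * im0) / sum(im0) - 31
  if (abs(cx) > 0.05 || abs(cy) > 0.05) {
    du <- pupil_freq_step(grid, config)
    tilt <- -2 * pi * du * template_pixel_nm *
      (cx * grid$u + cy * grid$v) * grid$aperture_radius
    phase <- phase + tilt
    phase[!grid$aperture] <- 0
    cal_mask$phase <- phase
  }
  if (is.null(template_z_nm))
    template_z_nm <- seq(min(stack$z_nm), max(stack$z_nm), by = 100)
  out <- tetrapod_calibration(cal_mask, template_z_nm, config,
                              roi_px = template_roi_px,
                              pixel_nm = template_pixel_nm)
  out$error <- err_hist
  out$converged <- converged
  out
}

#' Tetrapod template calibration
#'
#' Builds the template stack used by correlation-based fiducial tracking:
#' PSF renders on the camera pixel grid over a fine z grid, from either a
#' designed mask or a retrieved pupil.
#'
#' @param mask A [build_mask()] mask (or retrieved-pupil mask).
#' @param z_nm Template z grid in nm (fine, e.g. 100 nm steps, spanning the
#'   nominal range).
#' @param config An [optical_config()].
#' @param roi_px Template side in pixels.
#' @param pixel_nm Camera pixel size in nm.
#' @return A `tetrapod_calibration`: `templates` `[y, x, z]`, `z_nm`,
#'   `pixel_nm`, `phase`, `wavelength_nm`.
#' @export
tetrapod_calibration <- function(mask, z_nm, config = optical_config(),
                                 roi_px = 41,
                                 pixel_nm = config$effective_pixel_nm) {
  st <- psf_stack(mask, z_nm, config, roi_px = roi_px, pixel_nm = pixel_nm)
  structure(list(templates = st$images, z_nm = z_nm, pixel_nm = pixel_nm,
                 phase = mask$phase, wavelength_nm = config$emission_wavelength,
                 mask = mask, config = config),
            class = "tetrapod_calibration")
}

#' @export
print.tetrapod_calibration <- function(x, ...) {
  cat(sprintf(
    "<tetrapod_calibration> %d templates, z %g..%g nm, %.0f nm pixels\n",
    length(x$z_nm), min(x$z_nm), max(x$z_nm), x$pixel_nm))
  invisible(x)
}

## Normalized cross-correlation map of a frame against a (smaller) template.
## Returns the NCC coefficient at every valid template-center position
## (same size as frame; borders where the template overhangs are -Inf).
ncc_map <- function(frame, tmpl) {
  t0 <- tmpl - mean(tmpl)
  tnorm <- sqrt(sum(t0^2))
  npix <- length(tmpl)
  num <- filter2_fft(frame, t0)
  ones <- matrix(1, nrow(tmpl), ncol(tmpl))
  s1 <- filter2_fft(frame, ones)
  s2 <- filter2_fft(frame^2, ones)
  varloc <- pmax(s2 - s1^2 / npix, 0)
  den <- sqrt(varloc) * tnorm
  out <- ifelse(den > 0, num / den, 0)
  hy <- (nrow(tmpl) - 1) / 2
  hx <- (ncol(tmpl) - 1) / 2
  out[c(seq_len(hy), nrow(out) - seq_len(hy) + 1), ] <- -Inf
  out[, c(seq_len(hx), ncol(out) - seq_len(hx) + 1)] <- -Inf
  out
}

parabolic_offset <- function(ym, y0, yp) {
  d <- ym - 2 * y0 + yp
  if (d >= 0) return(0)
  off <- 0.5 * (ym - yp) / d
  max(-0.5, min(0.5, off))
}

#' Track a fiducial bead in one frame
#'
#' z by maximizing the normalized cross-correlation against the template
#' stack with parabolic sub-step interpolation; xy by sub-pixel (parabolic)
#' refinement of the best template's correlation peak. With a previous
#' position the search is restricted around it; otherwise a global search
#' over a decimated template set seeds the refinement.
#'
#' @param frame Photon-unit frame (matrix `[y, x]`).
#' @param calibration A [tetrapod_calibration()].
#' @param prev Optional previous position `c(x_nm, y_nm, z_nm)` (z =
#'   defocus) seeding the search.
#' @param search_z_nm Half-width of the z search window around `prev`.
#' @param min_quality Correlation floor below which the frame is declared a
#'   dropout (`ok = FALSE`).
#' @param refine Refine the correlation estimate by full-PSF-model maximum
#'   likelihood ([refine_localization()] with the calibration's pupil),
#'   removing the sub-pixel/sub-step interpolation bias of the correlation
#'   stage (default TRUE).
#' @return `list(x_nm, y_nm, z_nm, quality, ok)`; xy in field coordinates
#'   (nm, origin at the field center), z the defocus in nm.
#' @export
track_fiducial <- function(frame, calibration, prev = NULL,
                           search_z_nm = 600, min_quality = 0.35,
                           refine = TRUE) {
  zg <- calibration$z_nm
  px <- calibration$pixel_nm
  if (is.null(prev)) {
    idx <- unique(c(seq(1, length(zg), by = 3), length(zg)))
  } else {
    idx <- which(abs(zg - prev[3]) <= search_z_nm)
    if (length(idx) == 0) idx <- seq_along(zg)
  }
  best <- list(v = -Inf, i = NA, map = NULL)
  for (i in idx) {
    m <- ncc_map(frame, calibration$templates[, , i])
    v <- max(m)
    if (v > best$v) best <- list(v = v, i = i, map = m)
  }
  ## refine z over immediate template neighbors at the best xy
  i <- best$i
  pk <- unname(which(best$map == best$v, arr.ind = TRUE)[1, ])
  cc_at <- function(j) {
    if (j == i) return(best$v)
    m <- ncc_map(frame, calibration$templates[, , j])
    m[pk[1], pk[2]]
  }
  if (i > 1 && i < length(zg)) {
    vm <- cc_at(i - 1); vp <- cc_at(i + 1)
    ## if a neighbor beats the current best, step to it first
    while ((vm > best$v || vp > best$v) && i > 1 && i < length(zg)) {
      i <- if (vm > vp) i - 1 else i + 1
      m <- ncc_map(frame, calibration$templates[, , i])
      best <- list(v = max(m), i = i, map = m)
      pk <- unname(which(m == best$v, arr.ind = TRUE)[1, ])
      if (i == 1 || i == length(zg)) break
      vm <- cc_at(i - 1); vp <- cc_at(i + 1)
    }
  }
  z <- zg[i]
  if (i > 1 && i < length(zg)) {
    vm <- cc_at(i - 1); vp <- cc_at(i + 1)
    z <- z + parabolic_offset(vm, best$v, vp) * (zg[2] - zg[1])
  }
  m <- best$map
  dy <- dx <- 0
  if (pk[1] > 1 && pk[1] < nrow(m) && is.finite(m[pk[1] - 1, pk[2]]) &&
        is.finite(m[pk[1] + 1, pk[2]]))
    dy <- parabolic_offset(m[pk[1] - 1, pk[2]], m[pk[1], pk[2]],
                           m[pk[1] + 1, pk[2]])
  if (pk[2] > 1 && pk[2] < ncol(m) && is.finite(m[pk[1], pk[2] - 1]) &&
        is.finite(m[pk[1], pk[2] + 1]))
    dx <- parabolic_offset(m[pk[1], pk[2] - 1], m[pk[1], pk[2]],
                           m[pk[1], pk[2] + 1])
  cy <- (nrow(frame) + 1) / 2
  cx <- (ncol(frame) + 1) / 2
  out <- list(x_nm = unname((pk[2] + dx - cx) * px),
              y_nm = unname((pk[1] + dy - cy) * px),
              z_nm = unname(z), quality = best$v,
              ok = best$v >= min_quality)
  if (refine && out$ok && !is.null(calibration$mask)) {
    half <- (dim(calibration$templates)[1] - 1) / 2
    ys <- (pk[1] - half):(pk[1] + half)
    xs <- (pk[2] - half):(pk[2] + half)
    if (all(ys >= 1 & ys <= nrow(frame)) && all(xs >= 1 & xs <= ncol(frame))) {
      roi <- frame[ys, xs]
      bg0 <- stats::median(frame)
      rf <- refine_localization(
        roi, calibration$mask,
        init = list(x_nm = out$x_nm - (pk[2] - cx) * px,
                    y_nm = out$y_nm - (pk[1] - cy) * px,
                    z_nm = out$z_nm,
                    photons = max(sum(roi - bg0), 100), background = bg0),
        config = calibration$config, pixel_nm = px)
      if (rf$converged) {
        out$x_nm <- (pk[2] - cx) * px + rf$x_nm
        out$y_nm <- (pk[1] - cy) * px + rf$y_nm
        out$z_nm <- rf$z_nm
      }
    }
  }
  out
}

#' Track the fiducial through all fiducial frames of a stream
#'
#' @param stream A [simulate_stream()] result.
#' @param calibration A [tetrapod_calibration()].
#' @param offset_map Dark-offset map or scalar (default: camera nominal).
#' @return A `fiducial_track` `data.frame(frame, slice, x_nm, y_nm, z_nm,
#'   quality, ok)`, z being apparent defocus; dropout frames carry the
#'   interpolated position with `ok = FALSE`.
#' @export
track_fiducial_stream <- function(stream, calibration, offset_map = NULL) {
  frames <- which(stream$schedule$role == "fiducial")
  if (is.null(offset_map) && !is.null(stream$camera))
    offset_map <- stream$camera$offset
  prev <- NULL
  prev_nominal <- NULL
  rows <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    f <- frames[k]
    fr <- stream$frames[, , f]
    if (!is.null(stream$camera))
      fr <- counts_to_photons(subtract_dark(fr, offset_map), stream$camera)
    nominal <- stream$schedule$focal_z_um[f] * 1000
    ## a commanded focal step (slice change) shifts the bead's apparent
    ## defocus; move the search seed with it
    if (!is.null(prev) && !is.null(prev_nominal))
      prev[3] <- prev[3] - (nominal - prev_nominal)
    prev_nominal <- nominal
    tr <- track_fiducial(fr, calibration, prev = prev)
    if (tr$ok) prev <- c(tr$x_nm, tr$y_nm, tr$z_nm)
    rows[[k]] <- data.frame(frame = f, slice = stream$schedule$slice[f],
                            x_nm = tr$x_nm, y_nm = tr$y_nm, z_nm = tr$z_nm,
                            focal_nominal_nm = stream$schedule$focal_z_um[f] * 1000,
                            quality = tr$quality, ok = tr$ok)
  }
  out <- do.call(rbind, rows)
  ## interpolate across dropouts
  if (any(!out$ok) && sum(out$ok) >= 2) {
    for (col in c("x_nm", "y_nm", "z_nm")) {
      out[[col]][!out$ok] <- stats::approx(out$frame[out$ok],
                                           out[[col]][out$ok],
                                           out$frame[!out$ok], rule = 2)$y
    }
  }
  class(out) <- c("fiducial_track", "data.frame")
  out
}

#' Quality report for a fiducial track
#'
#' @param track A `fiducial_track` (>= 2 points).
#' @param jump_nm Per-axis step threshold flagged as a jump (default 250).
#' @return List with `dropout_fraction`, per-axis robust scatter (`mad`)
#'   after linear detrending, and `jumps` (frame indices of flagged steps).
#' @export
track_quality <- function(track, jump_nm = 250) {
  stopifnot(nrow(track) >= 2)
  detrended <- function(v) {
    stats::residuals(stats::lm(v ~ track$frame))
  }
  sc <- c(x = stats::mad(detrended(track$x_nm)),
          y = stats::mad(detrended(track$y_nm)),
          z = stats::mad(detrended(track$z_nm)))
  steps <- pmax(abs(diff(track$x_nm)), abs(diff(track$y_nm)),
                abs(diff(track$z_nm)))
  list(dropout_fraction = mean(!track$ok),
       scatter_nm = sc,
       jumps = track$frame[-1][steps > jump_nm])
}

#' Tracking-based axial feedback measurement for the simulator
#'
#' Returns a closure suitable as the `measure` element of
#' [simulate_stream()]'s `feedback` argument: it tracks the bead in each
#' fiducial photon-frame with the supplied calibration and reports its
#' apparent defocus.
#'
#' @param calibration A [tetrapod_calibration()].
#' @return `function(photon_frame, focal_z_nm) -> z_nm` (apparent defocus).
#' @export
make_feedback_tracker <- function(calibration) {
  prev <- NULL
  prev_focal <- NULL
  function(photon_frame, focal_z_nm) {
    ## commanded focal moves (slice steps, feedback corrections) shift the
    ## bead's apparent defocus; move the search seed accordingly
    if (!is.null(prev) && !is.null(prev_focal))
      prev[3] <<- prev[3] - (focal_z_nm - prev_focal)
    prev_focal <<- focal_z_nm
    tr <- track_fiducial(photon_frame, calibration, prev = prev)
    if (tr$ok) prev <<- c(tr$x_nm, tr$y_nm, tr$z_nm)
    tr$z_nm
  }
}
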