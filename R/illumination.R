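#' Tilted Gaussian light-sheet geometry
#'
#' Parameters of the illumination sheet: an elliptical Gaussian beam focused
#' in one dimension only, propagating across the field at a small downward
#' tilt. The thickness (waist radius) follows the hyperbolic Gaussian-beam
#' law `w(s) = w0 sqrt(1 + (2s/b)^2)` parameterized by the configured
#' confocal parameter `b`; waist and confocal parameter are treated as two
#' independent measured quantities of the real (mildly aberrated) sheet
#' rather than being derived from one another.
#'
#' @param waist_um 1/e^2 thickness (waist radius) of the sheet in um.
#' @param width_um 1/e^2 half-width of the sheet (transverse, in-plane) in um.
#' @param confocal_um Confocal parameter (twice the Rayleigh range) in um.
#' @param tilt_deg Downward tilt of the propagation axis in degrees.
#' @param wavelength_nm Illumination wavelength in nm (metadata).
#' @param center_z_um Height of the sheet center above the coverslip at the
#'   field center (x = 0) in um.
#' @param waist_offset_um Position of the waist along the propagation axis
#'   relative to the field center, in um.
#' @return A `sheet_params` object.
#' @export
sheet_params <- function(waist_um = 2.1, width_um = 19, confocal_um = 73,
                         tilt_deg = 10, wavelength_nm = 647,
                         center_z_um = 0, waist_offset_um = 0) {
  stopifnot(waist_um > 0, width_um >= waist_um,
            tilt_deg >= 0, tilt_deg < 45, confocal_um > 0)
  structure(list(waist_um = waist_um, width_um = width_um,
                 confocal_um = confocal_um, tilt_deg = tilt_deg,
                 wavelength_nm = wavelength_nm, center_z_um = center_z_um,
                 waist_offset_um = waist_offset_um),
            class = "sheet_params")
}

#' Illumination field: epi or tilted light sheet
#'
#' @param mode `"epi"` (z-uniform over the simulated volume) or `"sheet"`.
#' @param sheet A [sheet_params()] (sheet mode only).
#' @param peak_intensity Peak intensity in arbitrary units (scales
#'   [intensity_at()]).
#' @return An `illumination_field` object.
#' @export
illumination_field <- function(mode = c("sheet", "epi"), sheet = sheet_params(),
                               peak_intensity = 1) {
  mode <- match.arg(mode)
  structure(list(mode = mode,
                 sheet = if (mode == "sheet") sheet else NULL,
                 peak_intensity = peak_intensity),
            class = "illumination_field")
}

#' Relative illumination intensity at a point
#'
#' For the sheet, the point is expressed in the beam frame (propagation axis
#' tilted downward by the tilt angle about the width axis): Gaussian in the
#' sheet-normal coordinate with propagation-dependent thickness `w(s)`, and
#' Gaussian in the width coordinate; the `w0/w(s)` amplitude factor conserves
#' beam power along propagation. Epi mode is constant.
#'
#' @param field An [illumination_field()].
#' @param x_nm,y_nm,z_nm Point coordinates in nm (vectors recycle; x along
#'   the sheet propagation's horizontal projection, z height above the
#'   coverslip).
#' @return Relative intensity (1 at the sheet waist center times
#'   `peak_intensity`).
#' @export
intensity_at <- function(field, x_nm, y_nm = 0, z_nm = 0) {
  if (field$mode == "epi")
    return(rep_len(field$peak_intensity, max(length(x_nm), length(y_nm),
                                             length(z_nm))))
  sh <- field$sheet
  tau <- sh$tilt_deg * pi / 180
  x <- x_nm / 1000 - sh$waist_offset_um
  z <- z_nm / 1000 - sh$center_z_um
  y <- y_nm / 1000
  ## beam frame: propagation p = (cos tau, 0, -sin tau),
  ## sheet normal m = (sin tau, 0, cos tau), width axis = y
  s <- x * cos(tau) - z * sin(tau)
  nrm <- x * sin(tau) + z * cos(tau)
  zr <- sh$confocal_um / 2
  w <- sh$waist_um * sqrt(1 + (s / zr)^2)
  field$peak_intensity * (sh$waist_um / w) *
    exp(-2 * nrm^2 / w^2) * exp(-2 * y^2 / sh$width_um^2)
}

#' Axial scan positions for slice-by-slice acquisition
#'
#' The sheet (and, paired with it, the detection focal plane) is stepped
#' through the sample in equal axial increments; each position defines one
#' acquisition slice.
#'
#' @param start_um,stop_um First and last axial offset in um.
#' @param step_um Step in um (> 0).
#' @return `data.frame(slice, sheet_z_um, focal_z_um)` with the focal plane
#'   moved together with the sheet.
#' @export
scan_positions <- function(start_um, stop_um, step_um = 1) {
  stopifnot(step_um > 0)
  if (stop_um < start_um) stop("empty scan range")
  z <- seq(start_um, stop_um, by = step_um)
  data.frame(slice = seq_along(z), sheet_z_um = z, focal_z_um = z)
}

#' Mean out-of-focus background per camera pixel
#'
#' Integrates labeled-emitter density times illumination intensity over a
#' uniform slab phantom by deterministic quadrature, assuming the defocused
#' PSF spread redistributes each out-of-focus emitter's photons across the
#' field without loss (geometric-optics blur; photons stay on the detector).
#' The mean background per pixel is then independent of the blur kernel.
#'
#' @param field An [illumination_field()].
#' @param slab `list(z_min_um, z_max_um, density_um3)` — a uniformly labeled
#'   slab with `density_um3` emitters per um^3.
#' @param photons_per_emitter Expected photons emitted per out-of-focus
#'   emitter per frame at unit relative intensity.
#' @param config An [optical_config()] (sets the pixel area).
#' @param fov_um Field half-extent in um used to average the sheet profile
#'   laterally (tilt makes intensity x-dependent).
#' @param n_xy Lateral quadrature points per axis.
#' @param tol Relative tolerance of the axial quadrature refinement.
#' @return Photons per pixel per frame (deterministic).
#' @export
background_rate <- function(field, slab, photons_per_emitter = 1,
                            config = optical_config(), fov_um = 7.5,
                            n_xy = 5, tol = 1e-4) {
  stopifnot(slab$z_max_um >= slab$z_min_um, slab$density_um3 >= 0)
  if (slab$density_um3 == 0) return(0)
  px_um2 <- (config$effective_pixel_nm / 1000)^2
  xs <- seq(-fov_um, fov_um, length.out = n_xy)
  ## mean over the field of the z-integrated intensity, refined in z
  layer_integral <- function(n_z) {
    zs <- seq(slab$z_min_um, slab$z_max_um, length.out = n_z)
    dz <- (slab$z_max_um - slab$z_min_um) / (n_z - 1)
    tot <- 0
    for (x in xs) {
      iv <- intensity_at(field, x * 1000, 0, zs * 1000)
      tot <- tot + sum((iv[-1] + iv[-n_z]) / 2) * dz
    }
    tot / length(xs)
  }
  n_z <- 101
  est <- layer_integral(n_z)
  repeat {
    n_z <- 2 * n_z - 1
    nxt <- layer_integral(n_z)
    if (abs(nxt - est) <= tol * max(abs(nxt), 1e-12) || n_z > 1e5) {
      if (n_z > 1e5) warning("background quadrature did not converge to tol")
      est <- nxt
      break
    }
    est <- nxt
  }
  slab$density_um3 * est * photons_per_emitter * px_um2
}

#' Signal-to-background ratio
#'
#' Peak-pixel signal over mean background per pixel, computed identically for
#' both illumination modes.
#'
#' @param signal_photons Photons from the in-focus molecule in one frame.
#' @param background_per_px Background photons per pixel per frame.
#' @param peak_fraction Fraction of the signal landing in the brightest pixel
#'   (from the PSF model, e.g. `max(render_emitter(...))`).
#' @return Dimensionless SBR; `Inf` (with a warning) at zero background, 0 at
#'   zero signal.
#' @export
sbr <- function(signal_photons, background_per_px, peak_fraction = 1) {
  stopifnot(background_per_px >= 0)
  if (signal_photons == 0) return(0)
  if (background_per_px == 0) {
    warning("zero background: SBR is infinite")
    return(Inf)
  }
  signal_photons * peak_fraction / background_per_px
}
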