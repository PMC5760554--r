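#' Optical configuration of the detection path
#'
#' Bundles the parameters of the high-NA detection objective and the 4f relay
#' that every PSF computation needs. Lengths are stored in the units a
#' microscopist quotes them in: wavelength in nm, 4f focal length in mm,
#' camera pixel pitch in um. The effective object-plane pixel
#' (`pitch / magnification`) is derived and cached in nm.
#'
#' @param numerical_aperture NA of the detection objective (dimensionless).
#' @param magnification Total magnification onto the camera (dimensionless).
#' @param emission_wavelength Emission wavelength in nm.
#' @param immersion_index Refractive index of the immersion medium
#'   (oil, 1.518 by default). Index mismatch into the sample is ignored.
#' @param focal_length_4f Focal length of the 4f relay lenses in mm. Sets the
#'   physical scale of the Fourier plane, see [fourier_plane_diameter()].
#' @param camera_pixel_pitch Physical camera pixel pitch in um.
#'
#' @return An object of class `optical_config`.
#' @examples
#' cfg <- optical_config()
#' cfg$effective_pixel_nm  # 160 nm at 16 um pitch and 100x
#' @export
optical_config <- function(numerical_aperture = 1.4,
                           magnification = 100,
                           emission_wavelength = 670,
                           immersion_index = 1.518,
                           focal_length_4f = 90,
                           camera_pixel_pitch = 16) {
  stopifnot(numerical_aperture > 0,
            emission_wavelength > 0,
            focal_length_4f > 0,
            camera_pixel_pitch > 0)
  if (numerical_aperture >= immersion_index)
    stop("numerical aperture must be smaller than the immersion index")
  if (magnification <= numerical_aperture)
    stop("magnification must exceed the numerical aperture (Abbe sine geometry)")
  structure(list(
    numerical_aperture = numerical_aperture,
    magnification = magnification,
    emission_wavelength = emission_wavelength,
    immersion_index = immersion_index,
    focal_length_4f = focal_length_4f,
    camera_pixel_pitch = camera_pixel_pitch,
    effective_pixel_nm = camera_pixel_pitch * 1000 / magnification
  ), class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat(sprintf(
    "<optical_config> NA %.2f, M %gx, lambda %g nm, n %g, f4f %g mm, pixel %g um (%.1f nm eff.)\n",
    x$numerical_aperture, x$magnification, x$emission_wavelength,
    x$immersion_index, x$focal_length_4f, x$camera_pixel_pitch,
    x$effective_pixel_nm))
  invisible(x)
}

#' Electric-field diameter at the Fourier plane of a 4f relay
#'
#' Under the Abbe sine condition the emitted field fills a disc of diameter
#' \deqn{d_E = \frac{2 f_{4f} \mathrm{NA}}{\sqrt{M^2 - \mathrm{NA}^2}}}
#' at the Fourier plane of the 4f system. A phase mask placed there must have
#' an active region at least this large; overfilling the mask leaves
#' unmodulated light in the image.
#'
#' @param config An [optical_config()], or a focal length in mm when `na` and
#'   `magnification` are given explicitly.
#' @param na,magnification Optional explicit NA and magnification, used when
#'   `config` is a bare focal length.
#' @return Diameter in the units of the focal length (mm).
#' @examples
#' fourier_plane_diameter(90, na = 1.4, magnification = 100)   # 2.5 mm
#' fourier_plane_diameter(150, na = 1.4, magnification = 100)  # 4.2 mm
#' @export
fourier_plane_diameter <- function(config, na = NULL, magnification = NULL) {
  if (inherits(config, "optical_config")) {
    f <- config$focal_length_4f
    na <- config$numerical_aperture
    magnification <- config$magnification
  } else {
    f <- config
    if (is.null(na) || is.null(magnification))
      stop("supply `na` and `magnification` with a bare focal length")
  }
  if (na >= magnification)
    stop("degenerate geometry: NA must be smaller than the magnification")
  2 * f * na / sqrt(magnification^2 - na^2)
}

#' Discretized pupil (Fourier) plane
#'
#' A square sampling grid for the pupil of the detection objective. The unit
#' disc (normalized radius 1 at the NA edge) is the aperture; the grid side
#' must be at least twice the aperture diameter so that FFT-based image
#' formation does not alias.
#'
#' @param n_side Grid side in samples.
#' @param aperture_radius Aperture radius in samples.
#' @return A `pupil_grid` with normalized coordinate fields `u`, `v` (aperture
#'   edge at radius 1), `rho`, `theta`, and logical `aperture` mask.
#' @export
pupil_grid <- function(n_side = 256, aperture_radius = 64) {
  stopifnot(n_side >= 4 * aperture_radius)
  xs <- seq_len(n_side) - (n_side / 2 + 1)
  u <- matrix(xs, n_side, n_side, byrow = TRUE) / aperture_radius
  v <- matrix(xs, n_side, n_side) / aperture_radius
  rho <- sqrt(u^2 + v^2)
  structure(list(
    n_side = n_side,
    aperture_radius = aperture_radius,
    u = u, v = v,
    rho = rho,
    theta = atan2(v, u),
    aperture = rho <= 1
  ), class = "pupil_grid")
}

#' @export
print.pupil_grid <- function(x, ...) {
  cat(sprintf("<pupil_grid> %d x %d samples, aperture radius %d samples\n",
              x$n_side, x$n_side, x$aperture_radius))
  invisible(x)
}

## Pupil-plane frequency step in cycles/nm: the aperture edge maps to the
## spatial-frequency cutoff NA/lambda.
pupil_freq_step <- function(grid, config) {
  config$numerical_aperture /
    (config$emission_wavelength * grid$aperture_radius)
}
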