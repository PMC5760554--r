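#' EM-CCD camera model
#'
#' Parameters of the electron-multiplying CCD detection chain. The EM
#' register is modeled by the standard gamma approximation: `n` detected
#' photoelectrons become `Gamma(shape = n, scale = gain)` output electrons,
#' which reproduces the mean gain and the excess-noise factor of sqrt(2).
#'
#' @param exposure_ms Exposure time per frame in ms.
#' @param em_gain Calibrated EM gain (>= 1).
#' @param quantum_efficiency Photon -> photoelectron conversion probability.
#' @param read_noise_e Read noise at the output amplifier, electrons RMS.
#' @param offset Bias offset in counts.
#' @param conversion Electrons per count (A/D conversion factor).
#' @param dark_frames Number of dark frames acquired for offset calibration.
#' @return A `camera_model` object.
#' @export
camera_model <- function(exposure_ms = 50, em_gain = 186,
                         quantum_efficiency = 0.9, read_noise_e = 10,
                         offset = 100, conversion = 10, dark_frames = 300) {
  stopifnot(exposure_ms > 0, em_gain >= 1,
            quantum_efficiency > 0, quantum_efficiency <= 1,
            read_noise_e >= 0, conversion > 0)
  structure(list(exposure_ms = exposure_ms, em_gain = em_gain,
                 quantum_efficiency = quantum_efficiency,
                 read_noise_e = read_noise_e, offset = offset,
                 conversion = conversion, dark_frames = dark_frames),
            class = "camera_model")
}

#' Apply the EM-CCD noise chain to an expected-photon image
#'
#' Shot noise (Poisson on detected photoelectrons), stochastic EM
#' amplification (gamma approximation), Gaussian read noise, A/D conversion
#' and offset, floored at zero and rounded to integer counts.
#'
#' @param photon_image Matrix of expected incident photons per pixel.
#' @param camera A [camera_model()].
#' @return Integer matrix of camera counts.
#' @export
apply_camera_noise <- function(photon_image, camera) {
  n <- length(photon_image)
  pe <- stats::rpois(n, camera$quantum_efficiency * as.numeric(photon_image))
  el <- numeric(n)
  nz <- pe > 0
  if (camera$em_gain > 1) {
    el[nz] <- stats::rgamma(sum(nz), shape = pe[nz], scale = camera$em_gain)
  } else {
    el[nz] <- pe[nz]
  }
  el <- el + stats::rnorm(n, 0, camera$read_noise_e)
  counts <- pmax(0, round(el / camera$conversion + camera$offset))
  matrix(as.integer(counts), nrow(photon_image), ncol(photon_image))
}

#' Simulate a set of dark frames
#'
#' Frames acquired with the shutter closed: offset plus read noise only.
#'
#' @param camera A [camera_model()].
#' @param dims Frame dimensions `c(ny, nx)`.
#' @param n_frames Number of dark frames (default from the camera model).
#' @return Integer array `[ny, nx, n_frames]` of counts.
#' @export
simulate_dark_frames <- function(camera, dims = c(32, 32),
                                 n_frames = camera$dark_frames) {
  out <- array(0L, c(dims, n_frames))
  zero <- matrix(0, dims[1], dims[2])
  for (i in seq_len(n_frames)) out[, , i] <- apply_camera_noise(zero, camera)
  out
}

#' Pixelwise offset map from dark frames
#'
#' The mean of the dark frames, subtracted from every frame (clamped at
#' zero) before any analysis.
#'
#' @param dark Array `[ny, nx, n]` of dark frames (n >= 2) or a list of
#'   matrices.
#' @return Matrix offset map in counts.
#' @export
dark_calibrate <- function(dark) {
  if (is.list(dark)) dark <- simplify2array(dark)
  if (length(dim(dark)) != 3 || dim(dark)[3] < 2)
    stop("need at least 2 dark frames")
  rowMeans(dark, dims = 2)
}

#' Subtract a dark-offset map from a frame
#'
#' @param frame Counts matrix.
#' @param offset_map Matrix from [dark_calibrate()] (or a scalar).
#' @return Offset-subtracted counts, clamped at zero.
#' @export
subtract_dark <- function(frame, offset_map) {
  pmax(frame - offset_map, 0)
}

#' Convert dark-subtracted counts to photoelectrons
#'
#' `photons = counts * conversion / em_gain`; the inverse of the mean EM-CCD
#' transfer. Input must already be dark-subtracted.
#'
#' @param frame Dark-subtracted counts (matrix or array).
#' @param camera A [camera_model()].
#' @return Frame in photoelectron units.
#' @export
counts_to_photons <- function(frame, camera) {
  frame * camera$conversion / camera$em_gain
}
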