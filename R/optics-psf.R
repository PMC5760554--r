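## Scalar-diffraction image formation.
##
## The emitted field at the pupil is a unit-amplitude disc times the mask
## phase times the high-NA defocus phase; the camera image is the squared
## modulus of its Fourier transform. Two renderers are provided:
##  * psf_at()        — full-field FFT render on the grid's natural pixel,
##                      used for calibration stacks and energy accounting;
##  * render_emitter()— direct (matrix-product) DFT onto an arbitrary camera
##                      pixel grid with sub-pixel emitter offsets, used by the
##                      frame-stream simulator and all fitting oracles.
## Image matrices are indexed [y, x] with y increasing with row index; axes
## are mathematical, and the lobe angle is measured counter-clockwise.

## High-NA defocus phase (radians) for axial position z_nm (object space,
## positive = emitter above the nominal focal plane; immersion index n).
defocus_phase <- function(grid, config, z_nm) {
  s <- pmin(grid$rho, 1) * config$numerical_aperture / config$immersion_index
  (2 * pi / config$emission_wavelength) * config$immersion_index * z_nm *
    sqrt(pmax(0, 1 - s^2))
}

## Complex pupil field for a mask at defocus z (aperture-limited).
pupil_field <- function(mask, config, z_nm, extra_phase = NULL) {
  grid <- mask$grid
  ph <- mask$phase + defocus_phase(grid, config, z_nm)
  if (!is.null(extra_phase)) ph <- ph + extra_phase
  ifelse(grid$aperture, 1, 0) * exp(1i * ph)
}

fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c((n1 %/% 2 + 1):n1, 1:(n1 %/% 2)), c((n2 %/% 2 + 1):n2, 1:(n2 %/% 2))]
}

#' PSF image at a given defocus
#'
#' Renders the full-field PSF by zero-padded FFT of the pupil field,
#' normalized to unit total intensity (energy normalization is exact by
#' Parseval's theorem, independent of defocus). The natural pixel of the
#' render is `lambda * R / (NA * n_pad)` nm, returned as an attribute.
#'
#' @param mask A [build_mask()] phase mask.
#' @param z_nm Defocus in nm (object space). Values beyond twice the nominal
#'   mask range are allowed but degrade gracefully.
#' @param config An [optical_config()].
#' @param pad Zero-padding factor for the FFT (default 2).
#' @param max_clip Maximum tolerated fraction of energy falling outside the
#'   central half-field; beyond this the grid is declared too small for the
#'   requested defocus and an error is raised.
#' @return Matrix of normalized intensity (sums to 1 over the full field),
#'   with attributes `pixel_nm` and `z_nm`. Centered: the emitter sits at
#'   matrix position (n/2 + 1, n/2 + 1).
#' @export
psf_at <- function(mask, z_nm, config = optical_config(), pad = 2,
                   max_clip = 0.05) {
  grid <- mask$grid
  p <- pupil_field(mask, config, z_nm)
  n <- grid$n_side
  np <- n * pad
  big <- matrix(0 + 0i, np, np)
  big[1:n, 1:n] <- p
  im <- abs(stats::fft(big))^2
  im <- fftshift2(im) / sum(im)
  ## energy-clipping guard: the PSF must live well inside the rendered field
  c0 <- np %/% 2 + 1
  h <- np %/% 4
  inner <- sum(im[(c0 - h):(c0 + h - 1), (c0 - h):(c0 + h - 1)])
  if (1 - inner > max_clip)
    stop(sprintf(
      "pupil grid too small for z = %g nm: %.1f%% of the PSF energy is clipped",
      z_nm, 100 * (1 - inner)))
  pixel_nm <- config$emission_wavelength * grid$aperture_radius /
    (config$numerical_aperture * np)
  structure(im, pixel_nm = pixel_nm, z_nm = z_nm)
}

#' Render an emitter's PSF onto a camera pixel grid
#'
#' Direct discrete Fourier sum of the pupil field evaluated at the camera
#' pixel centers, allowing arbitrary pixel pitch and sub-pixel emitter
#' offsets. Returns the fraction of the total emitted (collected) intensity
#' landing in each pixel, so multiplying by a photon count gives expected
#' photons per pixel.
#'
#' @param mask A [build_mask()] phase mask.
#' @param z_nm Defocus of the emitter in nm.
#' @param config An [optical_config()].
#' @param dx_nm,dy_nm Emitter offset from the ROI center in nm.
#' @param roi_px ROI side length in pixels (odd recommended).
#' @param pixel_nm Object-plane pixel size in nm (default from `config`).
#' @param field Optional precomputed [pupil_field()] for this z (caching aid).
#' @return `roi_px` x `roi_px` matrix of intensity fractions, `[y, x]`.
#' @export
render_emitter <- function(mask, z_nm, config = optical_config(),
                           dx_nm = 0, dy_nm = 0, roi_px = 23,
                           pixel_nm = config$effective_pixel_nm,
                           field = NULL) {
  grid <- mask$grid
  if (is.null(field)) field <- pupil_field(mask, config, z_nm)
  du <- pupil_freq_step(grid, config)      # cycles / nm per sample
  n <- grid$n_side
  fr <- (seq_len(n) - (n / 2 + 1)) * du
  ctr <- (roi_px + 1) / 2
  ys <- (seq_len(roi_px) - ctr) * pixel_nm - dy_nm
  xs <- (seq_len(roi_px) - ctr) * pixel_nm - dx_nm
  ay <- exp(2i * pi * outer(ys, fr))       # roi x n, y-frequency rows of field
  bx <- exp(2i * pi * outer(fr, xs))       # n x roi
  e <- ay %*% field %*% bx
  i_px <- abs(e)^2 * (du * pixel_nm)^2 / sum(grid$aperture)
  i_px
}

#' Through-focus PSF stack
#'
#' Renders the PSF on a camera-pixel ROI across a z grid; the in-silico
#' analogue of calibrating a PSF by axially scanning a bead.
#'
#' @inheritParams render_emitter
#' @param z_nm Vector of axial positions in nm (object space, relative to the
#'   nominal focal plane).
#' @return A `psf_stack`: list with `images` (array `[y, x, z]` of intensity
#'   fractions), `z_nm`, `pixel_nm`, and the mask kind.
#' @export
psf_stack <- function(mask, z_nm, config = optical_config(), roi_px = 31,
                      pixel_nm = config$effective_pixel_nm) {
  images <- array(0, c(roi_px, roi_px, length(z_nm)))
  for (i in seq_along(z_nm))
    images[, , i] <- render_emitter(mask, z_nm[i], config,
                                    roi_px = roi_px, pixel_nm = pixel_nm)
  structure(list(images = images, z_nm = z_nm, pixel_nm = pixel_nm,
                 kind = mask$kind), class = "psf_stack")
}

#' @export
print.psf_stack <- function(x, ...) {
  cat(sprintf("<psf_stack> %s mask, %d planes, z %g..%g nm, %.1f nm pixels\n",
              x$kind, length(x$z_nm), min(x$z_nm), max(x$z_nm), x$pixel_nm))
  invisible(x)
}

## Locate the two dominant lobes of a double-helix image by peak picking with
## centroid refinement. Returns centers in (row, col) units of the input
## matrix, ordered so that lobe 1 is the one with the larger centroid "y or
## rightmost" — ordering is arbitrary; angle handling downstream works mod 180.
find_lobe_pair <- function(im, exclude_px = max(3L, round(nrow(im) / 8)),
                           refine_px = 3L) {
  refine <- function(p) {
    w <- refine_px
    ys <- max(1, p[1] - w):min(nrow(im), p[1] + w)
    xs <- max(1, p[2] - w):min(ncol(im), p[2] + w)
    s <- im[ys, xs]
    s <- pmax(s - min(s), 0)
    if (sum(s) == 0) return(as.numeric(p))
    c(sum(row(s) * s) / sum(s) + ys[1] - 1, sum(col(s) * s) / sum(s) + xs[1] - 1)
  }
  p1 <- which(im == max(im), arr.ind = TRUE)[1, ]
  masked <- im
  ys <- max(1, p1[1] - exclude_px):min(nrow(im), p1[1] + exclude_px)
  xs <- max(1, p1[2] - exclude_px):min(ncol(im), p1[2] + exclude_px)
  masked[ys, xs] <- -Inf
  p2 <- which(masked == max(masked), arr.ind = TRUE)[1, ]
  c1 <- refine(p1); c2 <- refine(p2)
  list(c1 = c1, c2 = c2,
       i1 = im[p1[1], p1[2]], i2 = im[p2[1], p2[2]])
}

## Angle (degrees, CCW, mathematical axes) of the line joining two lobe
## centers given as (row=y, col=x); defined mod 180.
lobe_angle_deg <- function(c1, c2) {
  (atan2(c2[1] - c1[1], c2[2] - c1[2]) * 180 / pi) %% 180
}

#' Double-helix angle versus defocus
#'
#' Renders the double-helix PSF across a z grid and measures the orientation
#' of the line joining the two lobes and their separation. Angles are
#' unwrapped (mod-180 jumps removed) and referenced so that z = 0 maps to 0
#' degrees, counter-clockwise positive; when the grid does not contain z = 0
#' the reference is interpolated.
#'
#' @param mask A double-helix [build_mask()].
#' @param z_nm Vector of axial positions in nm.
#' @param config An [optical_config()].
#' @param roi_px,pixel_nm Render geometry (finer pixels sharpen the angle
#'   estimate; default 80 nm).
#' @return `data.frame(z_nm, angle_deg, separation_nm)` plus attribute
#'   `monotone` (TRUE when the angle is strictly monotone over the grid).
#' @export
dh_angle_curve <- function(mask, z_nm, config = optical_config(),
                           roi_px = 41, pixel_nm = 80) {
  if (mask$kind != "double_helix")
    stop("dh_angle_curve needs a double_helix mask")
  raw <- sep <- numeric(length(z_nm))
  for (i in seq_along(z_nm)) {
    im <- render_emitter(mask, z_nm[i], config, roi_px = roi_px,
                         pixel_nm = pixel_nm)
    lb <- find_lobe_pair(im)
    raw[i] <- lobe_angle_deg(lb$c1, lb$c2)
    sep[i] <- sqrt(sum((lb$c1 - lb$c2)^2)) * pixel_nm
  }
  ord <- order(z_nm)
  ang <- raw
  ang[ord] <- unwrap_deg180(raw[ord])
  ref <- if (any(z_nm == 0)) ang[which(z_nm == 0)[1]] else
    stats::approx(z_nm[ord], ang[ord], xout = 0, rule = 2)$y
  ang <- ang - ref
  out <- data.frame(z_nm = z_nm, angle_deg = ang, separation_nm = sep)
  attr(out, "monotone") <- all(diff(ang[ord]) > 0) || all(diff(ang[ord]) < 0)
  out
}

## Unwrap a sequence of mod-180 angles into a continuous curve.
unwrap_deg180 <- function(a) {
  out <- a
  for (i in seq_along(a)[-1]) {
    d <- a[i] - out[i - 1]
    d <- (d + 90) %% 180 - 90
    out[i] <- out[i - 1] + d
  }
  out
}
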