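#' Calibrate the double-helix angle-to-z mapping from a bead z-stack
#'
#' The in-silico analogue of axially scanning a fiducial bead over the full
#' PSF range: each plane of the stack is fitted with the double-Gaussian
#' model, the lobe angles are unwrapped and referenced to 0 degrees at
#' z = 0, a low-order polynomial is fitted to angle(z), and the largest
#' strictly monotone window around focus becomes the valid range. The
#' per-z lobe separation and the per-z lateral wobble of the lobe midpoint
#' (applied later as an xy offset correction) are tabulated alongside.
#'
#' @param stack A [psf_stack()] (or list with `images` `[y, x, z]`, `z_nm`,
#'   `pixel_nm`) spanning the nominal range, containing a single bead.
#' @param poly_degree Degree of the angle(z) polynomial (default 5).
#' @return A `dh_calibration`: tables `z_nm`, `angle_deg`, `separation_nm`,
#'   `offset_x_nm`, `offset_y_nm`; `poly_coef` for angle(z); `valid_range_nm`
#'   (monotone window); `ref_angle_deg` (0 by convention at z = 0);
#'   `sigma_px`, `pixel_nm`.
#' @export
calibrate_dh <- function(stack, poly_degree = 5) {
  z <- stack$z_nm
  ord <- order(z)
  z <- z[ord]
  n <- length(z)
  pixel_nm <- stack$pixel_nm
  ang_raw <- sep_px <- mx <- my <- sig <- numeric(n)
  for (i in seq_len(n)) {
    im <- stack$images[, , ord[i]]
    lb <- find_lobe_pair(im)
    init <- list(angle_deg = lobe_angle_deg(lb$c1, lb$c2),
                 sep_px = sqrt(sum((lb$c1 - lb$c2)^2)))
    ft <- fit_double_gaussian(im, init = init, pixel_nm = pixel_nm)
    ang_raw[i] <- ft$angle_deg
    sep_px[i] <- ft$sep_px
    mx[i] <- ft$mx_px; my[i] <- ft$my_px
    sig[i] <- ft$sigma_px
  }
  ang <- unwrap_deg180(ang_raw)
  ref <- stats::approx(z, ang, xout = 0, rule = 2)$y
  ang <- ang - ref
  ## largest strictly monotone window containing z = 0 (or the stack center)
  d <- diff(ang)
  s <- sign(stats::median(d))
  if (s == 0) stop("calibration failure: flat angle-z curve")
  ok <- d * s > 0
  i0 <- which.min(abs(z))
  lo <- i0; hi <- i0
  while (lo > 1 && ok[lo - 1]) lo <- lo - 1
  while (hi < n && ok[hi]) hi <- hi + 1
  if (hi - lo < 3) stop("calibration failure: angle-z curve not monotone")
  win <- lo:hi
  pf <- stats::lm(ang[win] ~ stats::poly(z[win], poly_degree, raw = TRUE))
  ctr <- (dim(stack$images)[2] + 1) / 2
  structure(list(
    z_nm = z[win],
    angle_deg = ang[win],
    separation_nm = sep_px[win] * pixel_nm,
    offset_x_nm = (mx[win] - stats::approx(z, mx, 0, rule = 2)$y) * pixel_nm,
    offset_y_nm = (my[win] - stats::approx(z, my, 0, rule = 2)$y) * pixel_nm,
    poly_coef = unname(stats::coef(pf)),
    valid_range_nm = c(z[lo], z[hi]),
    ref_angle_deg = 0,
    raw_ref_deg = ref %% 180,
    direction = s,
    sigma_px = stats::median(sig),
    pixel_nm = pixel_nm,
    roi_center_px = ctr
  ), class = "dh_calibration")
}

#' @export
print.dh_calibration <- function(x, ...) {
  cat(sprintf(
    "<dh_calibration> valid z %g..%g nm, angle %g..%g deg, sep ~%.0f nm\n",
    x$valid_range_nm[1], x$valid_range_nm[2],
    round(min(x$angle_deg), 1), round(max(x$angle_deg), 1),
    stats::median(x$separation_nm)))
  invisible(x)
}

poly_eval <- function(coef, z) {
  drop(outer(z, seq_along(coef) - 1, `^`) %*% coef)
}

#' Invert the calibrated angle-to-z mapping
#'
#' Inversion goes through a monotone (Hyman-filtered) cubic spline of the
#' calibration table, which tracks the measured curve to interpolation
#' accuracy; the low-order polynomial fit is kept in the calibration for
#' reporting, but its residuals over a rippled angle curve (a few nm in z)
#' make it a poorer inverter.
#'
#' @param calibration A [calibrate_dh()] result.
#' @param angle_deg Raw lobe angle in degrees (mod 180, as fitted); the
#'   calibration's z = 0 reference orientation is subtracted internally.
#' @return z in nm, or `NA` when the angle falls outside the calibrated
#'   monotone range.
#' @export
z_from_angle <- function(calibration, angle_deg) {
  raw_ref <- if (!is.null(calibration$raw_ref_deg))
    calibration$raw_ref_deg else calibration$ref_angle_deg
  a <- angle_deg - raw_ref
  ## fold into the mod-180 branch nearest the calibrated curve
  amin <- min(calibration$angle_deg); amax <- max(calibration$angle_deg)
  a <- vapply(a, function(ai) {
    cand <- ai + c(-360, -180, 0, 180, 360)
    cand[which.min(pmax(amin - cand, cand - amax, 0))]
  }, numeric(1))
  ord <- order(calibration$angle_deg)
  inv <- stats::splinefun(calibration$angle_deg[ord], calibration$z_nm[ord],
                          method = "hyman")
  ifelse(a < amin - 1e-9 | a > amax + 1e-9, NA_real_, inv(a))
}

#' Convert a fitted lobe pair to a 3D localization
#'
#' The midpoint of the two lobes gives xy (plus the calibrated per-z lateral
#' offset correction); the lobe angle inverted through the calibration
#' polynomial gives z; the integrated Gaussian volumes give the photon count.
#'
#' @param fit A [fit_double_gaussian()] result.
#' @param calibration A [calibrate_dh()] result.
#' @param origin_nm Field coordinates (nm) of the ROI center pixel, length 2
#'   `(x, y)`; the returned position is origin + midpoint offset.
#' @param roi_center_px ROI center pixel (1-based); defaults to the
#'   calibration's.
#' @param frame,slice Bookkeeping indices carried into the record.
#' @return One-row `data.frame` localization: `x_nm, y_nm, z_nm, photons,
#'   background, angle_deg, separation_nm, asymmetry, residual, frame,
#'   slice, ok, reason`. `ok = FALSE` (z = NA) when the fit was rejected or
#'   the angle falls outside the calibrated range.
#' @export
lobe_pair_to_xyz <- function(fit, calibration, origin_nm = c(0, 0),
                             roi_center_px = calibration$roi_center_px,
                             frame = NA_integer_, slice = NA_integer_) {
  px <- calibration$pixel_nm
  out <- data.frame(
    x_nm = NA_real_, y_nm = NA_real_, z_nm = NA_real_,
    photons = fit$photons, background = fit$bg,
    angle_deg = fit$angle_deg,
    separation_nm = fit$sep_px * px,
    asymmetry = max(fit$a1, fit$a2) / max(min(fit$a1, fit$a2), 1e-12),
    residual = fit$residual,
    frame = frame, slice = slice, ok = FALSE, reason = NA_character_)
  if (fit$rejected) {
    out$reason <- fit$reason
    return(out)
  }
  if (fit$a1 <= 0 || fit$a2 <= 0) {
    out$reason <- "non-positive lobe amplitude"
    return(out)
  }
  z <- z_from_angle(calibration, fit$angle_deg)
  if (is.na(z)) {
    out$reason <- "angle outside calibrated range"
    return(out)
  }
  offx <- stats::approx(calibration$z_nm, calibration$offset_x_nm, z,
                        rule = 2)$y
  offy <- stats::approx(calibration$z_nm, calibration$offset_y_nm, z,
                        rule = 2)$y
  out$x_nm <- origin_nm[1] + (fit$mx_px - roi_center_px) * px - offx
  out$y_nm <- origin_nm[2] + (fit$my_px - roi_center_px) * px - offy
  out$z_nm <- z
  out$ok <- TRUE
  out
}
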