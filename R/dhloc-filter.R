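#' Default localization quality policy
#'
#' @param max_residual Maximum normalized fit residual (default 3; the EM-CCD excess-noise floor of this statistic is about 1.4).
#' @param max_asymmetry Maximum lobe intensity ratio (brighter / dimmer).
#' @param max_sep_dev Maximum relative deviation of the lobe separation from
#'   the calibrated separation at the fitted z.
#' @param min_photons Minimum integrated photons.
#' @param z_range_nm Accepted z interval (defaults to the calibration's
#'   valid range when filtering with a calibration available).
#' @return A `dh_filter_policy` list.
#' @export
dh_filter_policy <- function(max_residual = 3, max_asymmetry = 2.5,
                             max_sep_dev = 0.2, min_photons = 500,
                             z_range_nm = NULL) {
  structure(list(max_residual = max_residual, max_asymmetry = max_asymmetry,
                 max_sep_dev = max_sep_dev, min_photons = min_photons,
                 z_range_nm = z_range_nm), class = "dh_filter_policy")
}

#' Quality-filter a localization table
#'
#' Drops records failing the residual, asymmetry, separation-deviation,
#' photon-minimum, or z-range tests of the policy; each dropped record is
#' kept (with its reason) in the `dropped` attribute. An empty policy
#' (`NULL` thresholds) is the identity.
#'
#' @param locs Localization `data.frame` from [lobe_pair_to_xyz()] /
#'   [localize_stream()].
#' @param policy A [dh_filter_policy()] (or `list()` for no filtering).
#' @param calibration Optional [calibrate_dh()] result supplying the
#'   expected separation-vs-z and default z range.
#' @return The surviving rows, with attribute `dropped` (a `data.frame` with
#'   a `reason` column).
#' @export
filter_localizations <- function(locs, policy = dh_filter_policy(),
                                 calibration = NULL) {
  if (nrow(locs) == 0) return(locs)
  reason <- rep(NA_character_, nrow(locs))
  flag <- function(bad, why) reason[is.na(reason) & bad] <<- why
  # an empty policy is the identity; rejected fits are dropped only when
  # some policy is in force
  if (length(policy) > 0 && !is.null(locs$ok))
    flag(!locs$ok, ifelse(is.na(locs$reason[!locs$ok]),
                          "fit rejected", locs$reason[!locs$ok]))
  if (!is.null(policy$max_residual))
    flag(locs$residual > policy$max_residual, "residual")
  if (!is.null(policy$max_asymmetry))
    flag(locs$asymmetry > policy$max_asymmetry, "asymmetry")
  if (!is.null(policy$max_sep_dev) && !is.null(calibration)) {
    sep_exp <- stats::approx(calibration$z_nm, calibration$separation_nm,
                             locs$z_nm, rule = 2)$y
    flag(abs(locs$separation_nm - sep_exp) / sep_exp > policy$max_sep_dev,
         "separation deviation")
  }
  if (!is.null(policy$min_photons))
    flag(locs$photons < policy$min_photons, "photons")
  zr <- policy$z_range_nm
  if (is.null(zr) && !is.null(calibration)) zr <- calibration$valid_range_nm
  if (!is.null(zr))
    flag(is.na(locs$z_nm) | locs$z_nm < zr[1] | locs$z_nm > zr[2], "z range")
  keep <- is.na(reason)
  dropped <- locs[!keep, , drop = FALSE]
  dropped$reason <- reason[!keep]
  out <- locs[keep, , drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}

#' Empirical localization precision of a static emitter
#'
#' Per-axis standard deviation of repeated localizations after removing a
#' linear drift trend in frame order.
#'
#' @param locs Localization `data.frame` with `x_nm, y_nm, z_nm` (and
#'   optionally `frame` for the detrending order).
#' @param min_repeats Minimum number of repeats required (default 20).
#' @param detrend Remove a per-axis linear trend versus frame before taking
#'   the sd (drift removal).
#' @return Named numeric `c(x, y, z)` in nm.
#' @export
empirical_precision <- function(locs, min_repeats = 20, detrend = TRUE) {
  if (nrow(locs) < min_repeats)
    stop(sprintf("need at least %d repeated localizations", min_repeats))
  t <- if (!is.null(locs$frame) && !anyNA(locs$frame)) locs$frame
       else seq_len(nrow(locs))
  one <- function(v) {
    if (detrend) v <- stats::residuals(stats::lm(v ~ t))
    stats::sd(v)
  }
  c(x = one(locs$x_nm), y = one(locs$y_nm), z = one(locs$z_nm))
}

#' Localize every single-molecule frame of a stream
#'
#' The frame-level pipeline: dark-subtract, convert counts to photons,
#' detect double-helix candidates, fit each ROI with the double-Gaussian
#' model, and invert through the angle calibration. Fiducial and
#' reactivation frames are skipped for molecule detection (reactivation
#' frames can be included).
#'
#' @param stream A [simulate_stream()] result.
#' @param calibration A [calibrate_dh()] result.
#' @param offset_map Dark-offset map (matrix or scalar); defaults to the
#'   camera model's nominal offset. Ignored for noiseless streams.
#' @param roi_px Fit ROI size in pixels.
#' @param threshold Detection threshold policy, see [detect_candidates()].
#' @param include_reactivation Also analyze reactivation frames (default
#'   TRUE; molecules are excited on those frames too).
#' @param policy Optional [dh_filter_policy()] applied at the end.
#' @param refine Optional [build_mask()] mask enabling full-PSF-model
#'   maximum-likelihood refinement ([refine_localization()]) of every
#'   accepted fit; pass the mask the stream was imaged with.
#' @return Localization `data.frame` (one row per accepted fit; unfiltered
#'   records carry `ok`/`reason`).
#' @export
localize_stream <- function(stream, calibration, offset_map = NULL,
                            roi_px = 19,
                            threshold = list(method = "mad", k = 6),
                            include_reactivation = TRUE,
                            policy = NULL, refine = NULL) {
  px <- stream$fov$pixel_nm
  sep0 <- stats::approx(calibration$z_nm, calibration$separation_nm, 0,
                        rule = 2)$y
  sigma_nm <- calibration$sigma_px * calibration$pixel_nm
  roles <- c("sm", if (include_reactivation) "reactivation")
  frames <- which(stream$schedule$role %in% roles)
  if (is.null(offset_map) && !is.null(stream$camera))
    offset_map <- stream$camera$offset
  half <- (roi_px - 1) / 2
  ctr <- (roi_px + 1) / 2
  cx <- (stream$fov$nx + 1) / 2
  cy <- (stream$fov$ny + 1) / 2
  out <- list()
  for (f in frames) {
    fr <- stream$frames[, , f]
    if (!is.null(stream$camera)) {
      fr <- counts_to_photons(subtract_dark(fr, offset_map), stream$camera)
    }
    cand <- detect_candidates(fr, sep0, sigma_nm, px, threshold = threshold)
    for (i in seq_len(nrow(cand))) {
      y0 <- cand$y_px[i]; x0 <- cand$x_px[i]
      if (y0 - half < 1 || y0 + half > stream$fov$ny ||
            x0 - half < 1 || x0 + half > stream$fov$nx) next
      roi <- fr[(y0 - half):(y0 + half), (x0 - half):(x0 + half)]
      ft <- fit_double_gaussian(
        roi, init = list(angle_deg = cand$angle_deg[i], sep_px = sep0 / px,
                         sigma_px = calibration$sigma_px * calibration$pixel_nm / px),
        pixel_nm = px)
      origin <- c((x0 - cx) * px, (y0 - cy) * px)
      loc <- lobe_pair_to_xyz(
        ft, calibration, origin_nm = origin, roi_center_px = ctr,
        frame = f, slice = stream$schedule$slice[f])
      if (!is.null(refine) && isTRUE(loc$ok)) {
        rf <- refine_localization(
          roi, refine,
          init = list(x_nm = loc$x_nm - origin[1],
                      y_nm = loc$y_nm - origin[2],
                      z_nm = loc$z_nm, photons = loc$photons,
                      background = loc$background),
          config = if (is.null(stream$config)) optical_config()
                   else stream$config,
          pixel_nm = px)
        if (rf$converged) {
          loc$x_nm <- origin[1] + rf$x_nm
          loc$y_nm <- origin[2] + rf$y_nm
          loc$z_nm <- rf$z_nm
          loc$photons <- rf$photons
          loc$background <- rf$background
        }
      }
      out[[length(out) + 1]] <- loc
    }
  }
  locs <- if (length(out)) do.call(rbind, out) else
    data.frame(x_nm = numeric(), y_nm = numeric(), z_nm = numeric(),
               photons = numeric(), background = numeric(),
               angle_deg = numeric(), separation_nm = numeric(),
               asymmetry = numeric(), residual = numeric(),
               frame = integer(), slice = integer(), ok = logical(),
               reason = character())
  if (!is.null(policy)) locs <- filter_localizations(locs, policy, calibration)
  locs
}
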