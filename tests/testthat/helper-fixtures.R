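# Shared fixtures, built once per test run and cached. Two pupil grids are
# used: the full 256-sample grid for optics-level checks, and a 128-sample
# grid (aperture 32) for simulation-heavy tests, where the 4x cheaper
# renders matter and the PSF physics is unchanged.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name) {
  if (!exists(name, envir = .fx_cache)) {
    val <- switch(name,
      cfg = optical_config(),
      cfg_fid = optical_config(emission_wavelength = 605),
      grid = pupil_grid(),
      grid_small = pupil_grid(128, 32),
      dh = build_mask("double_helix", 2, fx("grid"), fx("cfg")),
      dh_small = build_mask("double_helix", 2, fx("grid_small"), fx("cfg")),
      dh_opt = optimize_dh_mask(fx("dh_small"), fx("cfg")),
      dh_cal = calibrate_dh(
        psf_stack(fx("dh_opt"), seq(-1200, 1200, by = 100), fx("cfg"),
                  roi_px = 25)),
      tp6 = build_mask("tetrapod", 6, fx("grid_small"), fx("cfg_fid")),
      tp6_cal = tetrapod_calibration(fx("tp6"), seq(-3000, 3000, by = 100),
                                     fx("cfg_fid"), roi_px = 41),
      clear = build_mask("clear", grid = fx("grid"), config = fx("cfg")),
      stop("unknown fixture: ", name))
    assign(name, val, envir = .fx_cache)
  }
  get(name, envir = .fx_cache)
}

# Localize one photon-unit ROI through the full dhloc chain (fit + invert,
# optional MLE refinement), returning the localization row.
localize_roi <- function(roi, calibration, mask = NULL, config = fx("cfg"),
                         pixel_nm = 160) {
  ctr <- (nrow(roi) + 1) / 2
  sep0 <- stats::approx(calibration$z_nm, calibration$separation_nm, 0,
                        rule = 2)$y
  ft <- fit_double_gaussian(
    roi, init = list(sep_px = sep0 / pixel_nm,
                     sigma_px = calibration$sigma_px *
                       calibration$pixel_nm / pixel_nm),
    pixel_nm = pixel_nm)
  loc <- lobe_pair_to_xyz(ft, calibration, origin_nm = c(0, 0),
                          roi_center_px = ctr)
  if (!is.null(mask) && isTRUE(loc$ok)) {
    rf <- refine_localization(
      roi, mask,
      init = list(x_nm = loc$x_nm, y_nm = loc$y_nm, z_nm = loc$z_nm,
                  photons = loc$photons, background = loc$background),
      config = config, pixel_nm = pixel_nm)
    if (rf$converged) {
      loc$x_nm <- rf$x_nm; loc$y_nm <- rf$y_nm; loc$z_nm <- rf$z_nm
      loc$photons <- rf$photons; loc$background <- rf$background
    }
  }
  loc
}
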