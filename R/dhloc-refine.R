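#' Refine a localization by full-PSF-model maximum likelihood
#'
#' The double-Gaussian estimator uses only the two lobes and therefore
#' leaves part of the photon information (the inter-lobe halo, the lobe
#' shape detail) on the table — empirically its precision sits 20-60% above
#' the Cramér–Rao bound. This refinement step maximizes the Poisson
#' likelihood of the full diffraction model (the mask's rendered PSF) over
#' (x, y, z, photons, background), seeded by the double-Gaussian estimate,
#' and reaches the bound. Implemented as least squares on Poisson deviance
#' residuals, which is exactly the Poisson MLE.
#'
#' In a real instrument the model would come from a phase-retrieved pupil;
#' here the simulator and the estimator share the shipped mask, which is the
#' self-consistency the in-silico design gives us.
#'
#' @param roi Photon-unit ROI matrix.
#' @param mask The PSF model's [build_mask()] phase mask (use the mask the
#'   data were imaged with, or a retrieved-pupil mask).
#' @param init `list(x_nm, y_nm, z_nm, photons, background)`: starting point
#'   (x, y relative to the ROI center pixel).
#' @param config An [optical_config()].
#' @param pixel_nm Pixel size of the ROI in nm.
#' @param max_iter Gauss-Newton iteration cap.
#' @return `list(x_nm, y_nm, z_nm, photons, background, converged,
#'   deviance)`; x, y relative to the ROI center.
#' @export
refine_localization <- function(roi, mask, init, config = optical_config(),
                                pixel_nm = config$effective_pixel_nm,
                                max_iter = 60) {
  roi_px <- nrow(roi)
  fn <- function(p) {
    mu <- render_emitter(mask, p[3], config, dx_nm = p[1], dy_nm = p[2],
                         roi_px = roi_px, pixel_nm = pixel_nm) * abs(p[4]) +
      abs(p[5])
    mu <- pmax(mu, 1e-9)
    d2 <- 2 * (mu - roi + ifelse(roi > 0, roi * log(roi / mu), 0))
    sign(roi - mu) * sqrt(pmax(d2, 0))
  }
  ft <- minpack.lm::nls.lm(
    par = c(init$x_nm, init$y_nm, init$z_nm, init$photons, init$background),
    fn = fn,
    control = minpack.lm::nls.lm.control(maxiter = max_iter,
                                         ptol = 1e-3, ftol = 1e-4))
  p <- ft$par
  list(x_nm = p[1], y_nm = p[2], z_nm = p[3], photons = abs(p[4]),
       background = abs(p[5]), converged = ft$info %in% 1:4,
       deviance = ft$deviance)
}
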