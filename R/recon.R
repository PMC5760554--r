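#' Render localizations into a 2D or 3D image
#'
#' Histogram mode bins localization counts into voxels; Gaussian mode splats
#' an isotropic kernel per point (sd = the supplied or per-point precision),
#' conserving total mass up to boundary clipping.
#'
#' @param locs Localization `data.frame` (`x_nm, y_nm` and, for 3D or other
#'   planes, `z_nm`).
#' @param voxel_nm Voxel size in nm: scalar, or length 2/3 per axis.
#' @param mode `"histogram"` or `"gaussian"`.
#' @param sigma_nm Splat sd in nm (scalar or per-point vector); required in
#'   Gaussian mode.
#' @param axes Which coordinates to render: `"xy"`, `"xz"`, `"yz"`, or
#'   `"xyz"` (3D array).
#' @param limits_nm Optional `list(c(min, max), ...)` per rendered axis;
#'   defaults to the data range padded by 3 sigma (or one voxel).
#' @return A `rendering`: list with `image` (matrix `[axis2, axis1]` or 3D
#'   array), `voxel_nm`, `origin_nm` (coordinate of the first voxel center),
#'   `axes`, `mode`.
#' @export
render_localizations <- function(locs, voxel_nm = 20,
                                 mode = c("histogram", "gaussian"),
                                 sigma_nm = NULL, axes = "xy",
                                 limits_nm = NULL) {
  mode <- match.arg(mode)
  stopifnot(nrow(locs) > 0)
  if (any(voxel_nm <= 0)) stop("zero voxel size")
  ax <- strsplit(axes, "")[[1]]
  cols <- paste0(ax, "_nm")
  stopifnot(all(cols %in% names(locs)))
  nd <- length(ax)
  voxel_nm <- rep_len(voxel_nm, nd)
  if (mode == "gaussian") {
    if (is.null(sigma_nm)) stop("gaussian mode needs sigma_nm")
    sigma_nm <- rep_len(sigma_nm, nrow(locs))
    pad <- 3 * max(sigma_nm)
  } else pad <- max(voxel_nm)
  crd <- lapply(cols, function(cn) locs[[cn]])
  if (is.null(limits_nm))
    limits_nm <- lapply(crd, function(v) range(v) + c(-pad, pad))
  dims <- vapply(seq_len(nd), function(d)
    as.integer(max(1, ceiling(diff(limits_nm[[d]]) / voxel_nm[d]))),
    integer(1))
  origin <- vapply(seq_len(nd), function(d)
    limits_nm[[d]][1] + voxel_nm[d] / 2, numeric(1))
  idx_of <- function(d, v) round((v - origin[d]) / voxel_nm[d]) + 1
  if (nd == 2) img <- matrix(0, dims[2], dims[1]) else
    img <- array(0, dims[c(2, 1, 3)])
  if (mode == "histogram") {
    i1 <- idx_of(1, crd[[1]]); i2 <- idx_of(2, crd[[2]])
    ok <- i1 >= 1 & i1 <= dims[1] & i2 >= 1 & i2 <= dims[2]
    if (nd == 3) {
      i3 <- idx_of(3, crd[[3]])
      ok <- ok & i3 >= 1 & i3 <= dims[3]
      for (k in which(ok)) img[i2[k], i1[k], i3[k]] <-
          img[i2[k], i1[k], i3[k]] + 1
    } else {
      for (k in which(ok)) img[i2[k], i1[k]] <- img[i2[k], i1[k]] + 1
    }
  } else {
    for (k in seq_len(nrow(locs))) {
      s <- sigma_nm[k]
      kern <- lapply(seq_len(nd), function(d) {
        c0 <- idx_of(d, crd[[d]][k])
        w <- ceiling(3 * s / voxel_nm[d])
        ii <- (c0 - w):(c0 + w)
        keep <- ii >= 1 & ii <= dims[d]
        centers <- origin[d] + (ii - 1) * voxel_nm[d]
        g <- exp(-(centers - crd[[d]][k])^2 / (2 * s^2))
        list(ii = ii[keep], g = (g / sum(g))[keep])
      })
      if (nd == 2) {
        img[kern[[2]]$ii, kern[[1]]$ii] <- img[kern[[2]]$ii, kern[[1]]$ii] +
          outer(kern[[2]]$g, kern[[1]]$g)
      } else {
        add <- outer(outer(kern[[2]]$g, kern[[1]]$g), kern[[3]]$g)
        img[kern[[2]]$ii, kern[[1]]$ii, kern[[3]]$ii] <-
          img[kern[[2]]$ii, kern[[1]]$ii, kern[[3]]$ii] + add
      }
    }
  }
  structure(list(image = img, voxel_nm = voxel_nm, origin_nm = origin,
                 axes = axes, mode = mode), class = "rendering")
}

#' @export
print.rendering <- function(x, ...) {
  cat(sprintf("<rendering> %s %s, %s voxels of %s nm\n", x$axes, x$mode,
              paste(dim(x$image), collapse = " x "),
              paste(x$voxel_nm, collapse = " x ")))
  invisible(x)
}

## Bilinear sample of a rendering's 2D image at physical coordinates (nm).
sample_rendering <- function(rend, a1_nm, a2_nm) {
  img <- rend$image
  f1 <- (a1_nm - rend$origin_nm[1]) / rend$voxel_nm[1] + 1
  f2 <- (a2_nm - rend$origin_nm[2]) / rend$voxel_nm[2] + 1
  i1 <- floor(f1); i2 <- floor(f2)
  t1 <- f1 - i1; t2 <- f2 - i2
  get <- function(r, c) {
    r <- pmin(pmax(r, 1), nrow(img))
    c <- pmin(pmax(c, 1), ncol(img))
    img[cbind(r, c)]
  }
  (1 - t2) * ((1 - t1) * get(i2, i1) + t1 * get(i2, i1 + 1)) +
    t2 * ((1 - t1) * get(i2 + 1, i1) + t1 * get(i2 + 1, i1 + 1))
}

#' Line-scan FWHM of a rendered structure
#'
#' Averages the rendering's intensity across the scan width perpendicular
#' to a line segment, fits a Gaussian plus constant to the averaged profile,
#' and returns the full width at half maximum `2 sqrt(2 ln 2) sigma`.
#'
#' @param rendering A 2D [render_localizations()] result.
#' @param from_nm,to_nm Segment endpoints in the rendering's axis
#'   coordinates (nm), length 2 each.
#' @param width_nm Averaging width perpendicular to the segment (>= one
#'   voxel).
#' @param n_samples Samples along the profile (default: one per half voxel).
#' @return FWHM in nm, with the fitted profile as attribute `fit`
#'   (`data.frame(s_nm, intensity, fitted)`).
#' @export
linescan_fwhm <- function(rendering, from_nm, to_nm, width_nm = 0,
                          n_samples = NULL) {
  stopifnot(length(dim(rendering$image)) == 2)
  v <- c(to_nm[1] - from_nm[1], to_nm[2] - from_nm[2])
  len <- sqrt(sum(v^2))
  u <- v / len
  w <- c(-u[2], u[1])
  if (is.null(n_samples))
    n_samples <- max(25, ceiling(2 * len / min(rendering$voxel_nm)))
  s <- seq(0, len, length.out = n_samples)
  n_w <- max(1, ceiling(width_nm / min(rendering$voxel_nm)) + 1)
  offs <- if (n_w == 1) 0 else seq(-width_nm / 2, width_nm / 2,
                                   length.out = n_w)
  prof <- rowMeans(vapply(offs, function(o) {
    sample_rendering(rendering,
                     from_nm[1] + s * u[1] + o * w[1],
                     from_nm[2] + s * u[2] + o * w[2])
  }, numeric(n_samples)))
  ## Gaussian + constant fit
  bg0 <- min(prof)
  a0 <- max(prof) - bg0
  m0 <- s[which.max(prof)]
  s0 <- max(len / 10, sum(prof - bg0 > a0 / 2) * (s[2] - s[1]) / 2.3548)
  fit <- minpack.lm::nls.lm(
    par = c(a0, m0, s0, bg0),
    fn = function(p) p[1] * exp(-(s - p[2])^2 / (2 * p[3]^2)) + p[4] - prof,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!fit$info %in% 1:4) stop("line-scan profile fit did not converge")
  p <- fit$par
  fwhm <- 2 * sqrt(2 * log(2)) * abs(p[3])
  attr(fwhm, "fit") <- data.frame(
    s_nm = s, intensity = prof,
    fitted = p[1] * exp(-(s - p[2])^2 / (2 * p[3]^2)) + p[4])
  fwhm
}

#' Signal-to-background ratio of a single-molecule image
#'
#' Background is estimated as the mean in an annulus around the PSF
#' footprint; the SBR is (peak pixel - background) / background.
#'
#' @param frame Photon-unit frame (matrix `[y, x]`).
#' @param center_px `c(y, x)` position of the molecule (pixels; from a
#'   localization or ground truth).
#' @param footprint_px PSF footprint radius in pixels; the peak is searched
#'   within it and the annulus spans `[2, 3] x` this radius by default.
#' @param annulus Multipliers `c(inner, outer)` of `footprint_px`.
#' @return Dimensionless SBR (0 for a flat frame).
#' @export
measure_sbr <- function(frame, center_px, footprint_px = 5,
                        annulus = c(2, 3)) {
  yy <- row(frame) - center_px[1]
  xx <- col(frame) - center_px[2]
  r <- sqrt(yy^2 + xx^2)
  inner <- r <= footprint_px
  ring <- r >= annulus[1] * footprint_px & r <= annulus[2] * footprint_px
  if (!any(ring)) stop("empty background annulus (frame too small)")
  bg <- mean(frame[ring])
  peak <- max(frame[inner])
  if (bg <= 0) return(if (peak > 0) Inf else 0)
  (peak - bg) / bg
}
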