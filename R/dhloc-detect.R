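## Candidate detection for double-helix frames: a matched filter built from
## two displaced Gaussian kernels is swept over a small set of trial lobe
## orientations; local maxima of the best-orientation response above
## threshold become candidate ROIs centered on the lobe-pair midpoint.

## FFT cross-correlation of an image with a centered kernel (same size out).
filter2_fft <- function(img, kernel) {
  ny <- nrow(img); nx <- ncol(img)
  ky <- nrow(kernel); kx <- ncol(kernel)
  py <- ny + ky - 1; px <- nx + kx - 1
  a <- matrix(0, py, px); a[1:ny, 1:nx] <- img
  b <- matrix(0, py, px); b[1:ky, 1:kx] <- kernel
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE)) /
    (py * px)
  ## with the kernel centered at cy = (ky+1)/2, the correlation value for
  ## image pixel i sits at circular index (i - cy) mod py
  cy <- (ky + 1) / 2
  cx <- (kx + 1) / 2
  idx_y <- ((1:ny) - cy) %% py + 1
  idx_x <- ((1:nx) - cx) %% px + 1
  cc[idx_y, idx_x]
}

dh_pair_kernel <- function(sep_px, angle_deg, sigma_px, size_px) {
  ctr <- (size_px + 1) / 2
  th <- angle_deg * pi / 180
  x1 <- ctr + sep_px / 2 * cos(th); y1 <- ctr + sep_px / 2 * sin(th)
  x2 <- ctr - sep_px / 2 * cos(th); y2 <- ctr - sep_px / 2 * sin(th)
  g <- function(x0, y0) {
    xx <- matrix(seq_len(size_px), size_px, size_px, byrow = TRUE)
    yy <- matrix(seq_len(size_px), size_px, size_px)
    exp(-((xx - x0)^2 + (yy - y0)^2) / (2 * sigma_px^2))
  }
  k <- g(x1, y1) + g(x2, y2)
  k - mean(k)
}

#' Detect double-helix candidates in a photon frame
#'
#' @param frame Dark-subtracted, photon-converted frame (matrix `[y, x]`).
#' @param sep_nm Expected lobe separation in nm (from the calibration).
#' @param sigma_nm Expected lobe width (Gaussian sd) in nm.
#' @param pixel_nm Object-plane pixel size in nm.
#' @param n_angles Number of trial orientations spanning 180 degrees.
#' @param threshold Threshold policy: `list(method = "mad", k = 6)` sets the
#'   response threshold at `median + k * mad` of the response map;
#'   `list(method = "absolute", value = v)` uses a fixed response value.
#' @param min_sep_px Minimum distance between accepted candidates (merged
#'   below this); defaults to the lobe separation.
#' @return `data.frame(y_px, x_px, angle_deg, response)` of candidate ROI
#'   centers (lobe-pair midpoints), possibly empty.
#' @export
detect_candidates <- function(frame, sep_nm, sigma_nm = 150,
                              pixel_nm = 160, n_angles = 8,
                              threshold = list(method = "mad", k = 6),
                              min_sep_px = NULL) {
  sep_px <- sep_nm / pixel_nm
  sigma_px <- sigma_nm / pixel_nm
  size <- 2 * ceiling(sep_px / 2 + 3 * sigma_px) + 1
  angles <- seq(0, 180, length.out = n_angles + 1)[-(n_angles + 1)]
  best <- matrix(-Inf, nrow(frame), ncol(frame))
  best_ang <- matrix(0, nrow(frame), ncol(frame))
  for (a in angles) {
    resp <- filter2_fft(frame, dh_pair_kernel(sep_px, a, sigma_px, size))
    upd <- resp > best
    best[upd] <- resp[upd]
    best_ang[upd] <- a
  }
  ## exclude positions where the kernel overhangs the frame (the zero
  ## padding there makes a zero-mean kernel respond to flat background)
  h <- (size - 1) / 2
  if (h >= 1) {
    edge_y <- c(seq_len(min(h, nrow(best))),
                nrow(best) - seq_len(min(h, nrow(best))) + 1)
    edge_x <- c(seq_len(min(h, ncol(best))),
                ncol(best) - seq_len(min(h, ncol(best))) + 1)
    best[edge_y, ] <- -Inf
    best[, edge_x] <- -Inf
  }
  interior <- best[is.finite(best)]
  thr <- switch(threshold$method,
    mad = stats::median(interior) + threshold$k * stats::mad(interior),
    absolute = threshold$value,
    stop("unknown threshold method"))
  ## floor against FFT round-off on (near-)constant frames
  thr <- max(thr, 1e-9 * sum(abs(frame)))
  if (is.null(min_sep_px)) min_sep_px <- 1.5 * sep_px
  ## local maxima above threshold, greedily accepted brightest-first
  cand <- which(best > thr, arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(data.frame(y_px = numeric(), x_px = numeric(),
                      angle_deg = numeric(), response = numeric()))
  is_max <- vapply(seq_len(nrow(cand)), function(i) {
    y <- cand[i, 1]; x <- cand[i, 2]
    ys <- max(1, y - 1):min(nrow(best), y + 1)
    xs <- max(1, x - 1):min(ncol(best), x + 1)
    best[y, x] >= max(best[ys, xs])
  }, TRUE)
  cand <- cand[is_max, , drop = FALSE]
  vals <- best[cand]
  ord <- order(-vals)
  cand <- cand[ord, , drop = FALSE]
  vals <- vals[ord]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      d <- sqrt((cand[(i + 1):nrow(cand), 1] - cand[i, 1])^2 +
                  (cand[(i + 1):nrow(cand), 2] - cand[i, 2])^2)
      keep[(i + 1):nrow(cand)][d < min_sep_px] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  data.frame(y_px = cand[, 1], x_px = cand[, 2],
             angle_deg = best_ang[cand], response = vals[keep])
}
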