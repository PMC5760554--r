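#' Axial feedback correction for one measurement
#'
#' The live-feedback law: the correction sent to the objective scanner is
#' the difference between the measured fiducial z and the setpoint. In the
#' simulator the correction takes effect on the frames after the fiducial
#' frame (one interleave period of latency).
#'
#' @param measured_z_nm Fiducial z measured on a fiducial frame.
#' @param setpoint_nm Target z.
#' @return Correction in nm (`measured - setpoint`, the amount the focal
#'   plane must move to re-center the bead).
#' @export
live_axial_feedback <- function(measured_z_nm, setpoint_nm) {
  measured_z_nm - setpoint_nm
}

#' Closed-loop axial feedback against a drift trajectory
#'
#' Pure arithmetic simulation of the feedback loop: the bead's apparent z is
#' the drift minus the accumulated correction; every `period` frames the
#' loop measures it (optionally with noise) and updates the correction,
#' applied with `latency` frames of delay. The residual (drift minus applied
#' correction) of a linear drift is a sawtooth bounded by
#' `period x drift rate` plus measurement noise.
#'
#' @param drift_z_nm Per-frame axial drift (vector, nm).
#' @param period Fiducial interleave period in frames.
#' @param latency Frames between measurement and application (default 1).
#' @param noise_nm Measurement noise sd (default 0).
#' @param setpoint_nm Feedback setpoint (default: apparent z at the first
#'   fiducial frame).
#' @return `data.frame(frame, drift_nm, correction_nm, residual_nm)`; a
#'   dropout (NA in `drift_z_nm`) holds the last correction.
#' @export
simulate_axial_feedback <- function(drift_z_nm, period = 20, latency = 1,
                                    noise_nm = 0, setpoint_nm = NULL) {
  n <- length(drift_z_nm)
  corr <- numeric(n)     # correction applied during each frame
  cur <- 0
  pending <- NULL        # c(frame_effective, value)
  meas_frames <- seq(period, n, by = period)
  set <- setpoint_nm
  for (f in seq_len(n)) {
    if (!is.null(pending) && f >= pending[1]) {
      cur <- pending[2]
      pending <- NULL
    }
    corr[f] <- cur
    if (f %in% meas_frames) {
      apparent <- drift_z_nm[f] - cur
      if (!is.na(apparent)) {
        meas <- apparent + if (noise_nm > 0) stats::rnorm(1, 0, noise_nm) else 0
        if (is.null(set)) set <- meas
        pending <- c(f + latency, cur + live_axial_feedback(meas, set))
      }  # dropout: hold last correction
    }
  }
  data.frame(frame = seq_len(n), drift_nm = drift_z_nm,
             correction_nm = corr, residual_nm = drift_z_nm - corr)
}

#' Build a per-frame drift trace from fiducial tracks
#'
#' Interpolates each bead's sampled positions (fiducial frames) linearly to
#' every frame, references them to zero at the first fiducial frame, and
#' combines multiple beads by inverse-variance weighting (variance from each
#' track's detrended scatter).
#'
#' Tracks record the bead's apparent defocus, which jumps when the focal
#' plane is commanded to a new slice; a `focal_nominal_nm` column (written
#' by [track_fiducial_stream()]) is added back so that the trace measures
#' drift in the sample frame and leaves intentional slice steps alone.
#'
#' @param tracks A `fiducial_track` or list of them (from
#'   [track_fiducial_stream()]).
#' @param frames Frame indices the trace must cover (e.g. `1:n_frames`).
#' @return A `drift_trace` `data.frame(frame, dx_nm, dy_nm, dz_nm)`.
#' @export
fiducial_drift_trace <- function(tracks, frames) {
  if (is.data.frame(tracks)) tracks <- list(tracks)
  per_axis <- function(col) {
    est <- matrix(NA_real_, length(frames), length(tracks))
    w <- numeric(length(tracks))
    for (b in seq_along(tracks)) {
      tr <- tracks[[b]]
      v <- tr[[col]]
      if (col == "z_nm" && !is.null(tr$focal_nominal_nm))
        v <- v + tr$focal_nominal_nm
      v <- v - v[1]
      est[, b] <- stats::approx(tr$frame, v, xout = frames, rule = 2)$y
      s <- stats::mad(stats::residuals(stats::lm(v ~ tr$frame)))
      w[b] <- 1 / max(s, 1)^2
    }
    drop(est %*% w) / sum(w)
  }
  structure(data.frame(frame = frames,
                       dx_nm = per_axis("x_nm"),
                       dy_nm = per_axis("y_nm"),
                       dz_nm = per_axis("z_nm")),
            class = c("drift_trace", "data.frame"))
}

#' Apply a drift trace to a localization table
#'
#' Subtracts the interpolated per-frame (dx, dy, dz) from each localization.
#' The returned table records (attribute `drift_applied`) that the trace has
#' been consumed, so accidentally re-applying the same trace is detectable.
#'
#' @param locs Localization `data.frame` with a `frame` column.
#' @param trace A [fiducial_drift_trace()] (must cover all frames present).
#' @return Corrected localization table.
#' @export
apply_drift_correction <- function(locs, trace) {
  if (nrow(locs) == 0) return(locs)
  if (isTRUE(attr(locs, "drift_applied")))
    warning("localizations already drift-corrected; applying another trace")
  if (any(!(locs$frame %in% trace$frame)) &&
      (min(locs$frame) < min(trace$frame) || max(locs$frame) > max(trace$frame)))
    stop("drift trace does not cover all localization frames")
  dx <- stats::approx(trace$frame, trace$dx_nm, locs$frame, rule = 2)$y
  dy <- stats::approx(trace$frame, trace$dy_nm, locs$frame, rule = 2)$y
  dz <- stats::approx(trace$frame, trace$dz_nm, locs$frame, rule = 2)$y
  locs$x_nm <- locs$x_nm - dx
  locs$y_nm <- locs$y_nm - dy
  locs$z_nm <- locs$z_nm - dz
  attr(locs, "drift_applied") <- TRUE
  locs
}

## Cross-correlate two z histograms over integer-bin lags and return the
## sub-bin (parabolic) peak lag in nm. Positive lag means `zb` sits higher
## than `za`.
histogram_xcorr_offset <- function(za, zb, bin_nm = 10, max_lag_nm = 300) {
  lo <- min(za, zb) - max_lag_nm
  hi <- max(za, zb) + max_lag_nm
  breaks <- seq(lo - bin_nm, hi + bin_nm, by = bin_nm)
  ha <- graphics::hist(za, breaks = breaks, plot = FALSE)$counts
  hb <- graphics::hist(zb, breaks = breaks, plot = FALSE)$counts
  max_lag <- ceiling(max_lag_nm / bin_nm)
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(l) {
    if (l >= 0) sum(ha[1:(length(ha) - l)] * hb[(1 + l):length(hb)])
    else sum(ha[(1 - l):length(ha)] * hb[1:(length(hb) + l)])
  }, numeric(1))
  i <- which.max(cc)
  off <- 0
  if (i > 1 && i < length(lags))
    off <- parabolic_offset(cc[i - 1], cc[i], cc[i + 1])
  (lags[i] + off) * bin_nm
}

## 3D variant: correlate (x, y, z)-binned histograms over z lags only. The
## lateral structure anchors the axial alignment, which matters for
## structures whose z marginal is featureless (a spherical shell's z
## marginal is uniform).
histogram_xcorr_offset_xyz <- function(a, b, bin_nm = 10, bin_xy_nm = 100,
                                       max_lag_nm = 300) {
  zlo <- min(a$z_nm, b$z_nm) - max_lag_nm
  zhi <- max(a$z_nm, b$z_nm) + max_lag_nm
  zbreaks <- seq(zlo - bin_nm, zhi + bin_nm, by = bin_nm)
  xlo <- min(a$x_nm, b$x_nm); xhi <- max(a$x_nm, b$x_nm)
  ylo <- min(a$y_nm, b$y_nm); yhi <- max(a$y_nm, b$y_nm)
  nx <- max(1, ceiling((xhi - xlo) / bin_xy_nm))
  ny <- max(1, ceiling((yhi - ylo) / bin_xy_nm))
  nz <- length(zbreaks) - 1
  idx <- function(d) {
    ix <- pmin(pmax(floor((d$x_nm - xlo) / bin_xy_nm) + 1, 1), nx)
    iy <- pmin(pmax(floor((d$y_nm - ylo) / bin_xy_nm) + 1, 1), ny)
    iz <- pmin(pmax(findInterval(d$z_nm, zbreaks), 1), nz)
    cbind(ix, iy, iz)
  }
  ha <- array(0L, c(nx, ny, nz)); hb <- array(0L, c(nx, ny, nz))
  ia <- idx(a); ib <- idx(b)
  for (r in seq_len(nrow(ia))) ha[ia[r, 1], ia[r, 2], ia[r, 3]] <-
    ha[ia[r, 1], ia[r, 2], ia[r, 3]] + 1L
  for (r in seq_len(nrow(ib))) hb[ib[r, 1], ib[r, 2], ib[r, 3]] <-
    hb[ib[r, 1], ib[r, 2], ib[r, 3]] + 1L
  max_lag <- ceiling(max_lag_nm / bin_nm)
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(l) {
    if (l >= 0) sum(ha[, , 1:(nz - l)] * hb[, , (1 + l):nz])
    else sum(ha[, , (1 - l):nz] * hb[, , 1:(nz + l)])
  }, numeric(1))
  i <- which.max(cc)
  off <- 0
  if (i > 1 && i < length(lags))
    off <- parabolic_offset(cc[i - 1], cc[i], cc[i + 1])
  (lags[i] + off) * bin_nm
}

#' Stitch axial slices of localizations
#'
#' Aligns each adjacent pair of slices by cross-correlating the z histograms
#' of their localizations within the overlap region (the engineered-PSF
#' axial range exceeds the scan step, so adjacent slices see the same
#' structure), takes the sub-bin parabolic peak as the residual offset, and
#' chains offsets from the first slice. Fiducial-track offsets, when given,
#' initialize/center the lag search.
#'
#' @param slices List of per-slice localization tables (each with `z_nm`
#'   relative to its own focal plane).
#' @param nominal_offset_nm Nominal focal-plane offset of each slice in nm
#'   (length = number of slices, e.g. `(slice - 1) * 1000`).
#' @param bin_nm Histogram bin (default 10 nm).
#' @param max_lag_nm Half-width of the residual search window (default 300).
#' @param init_offset_nm Optional per-slice initial offsets from fiducial
#'   tracks, same length/reference as `nominal_offset_nm`.
#' @param min_overlap Minimum localizations per slice inside the overlap to
#'   attempt cross-correlation; below this the initialization (or nominal)
#'   offset is used with a warning.
#' @param method `"z"` correlates 1D z histograms; `"xyz"` correlates 3D
#'   histograms over z lags, anchoring the axial alignment with the lateral
#'   structure (recommended for structures whose z marginal is flat, such
#'   as a spherical shell).
#' @param bin_xy_nm Lateral bin for `method = "xyz"`.
#' @return List with `merged` (single table; `z_nm` in the first slice's
#'   frame; provenance column `slice`), `offset_nm` (applied total offset
#'   per slice), `residual_nm` (detected misalignment per adjacent pair,
#'   positive when the upper slice sits too high; subtracted when merging),
#'   and `chained_residual_nm` (cumulative detected misalignment per slice).
#' @export
stitch_slices <- function(slices, nominal_offset_nm, bin_nm = 10,
                          max_lag_nm = 300, init_offset_nm = NULL,
                          min_overlap = 10, method = c("z", "xyz"),
                          bin_xy_nm = 100) {
  method <- match.arg(method)
  k <- length(slices)
  stopifnot(k >= 2, length(nominal_offset_nm) == k,
            all(diff(nominal_offset_nm) > 0))
  if (is.null(init_offset_nm)) init_offset_nm <- nominal_offset_nm
  residual <- numeric(k - 1)
  for (i in seq_len(k - 1)) {
    za <- slices[[i]]$z_nm + init_offset_nm[i]
    zb <- slices[[i + 1]]$z_nm + init_offset_nm[i + 1]
    lo <- max(min(za), min(zb))
    hi <- min(max(za), max(zb))
    ina <- za >= lo & za <= hi
    inb <- zb >= lo & zb <= hi
    if (sum(ina) < min_overlap || sum(inb) < min_overlap) {
      warning(sprintf(
        "slices %d-%d: empty overlap, falling back to fiducial/nominal offset",
        i, i + 1))
      residual[i] <- 0
    } else if (method == "z") {
      residual[i] <- histogram_xcorr_offset(za[ina], zb[inb], bin_nm,
                                            max_lag_nm)
    } else {
      da <- slices[[i]][ina, c("x_nm", "y_nm")]
      da$z_nm <- za[ina]
      db <- slices[[i + 1]][inb, c("x_nm", "y_nm")]
      db$z_nm <- zb[inb]
      residual[i] <- histogram_xcorr_offset_xyz(da, db, bin_nm, bin_xy_nm,
                                                max_lag_nm)
    }
  }
  chained <- c(0, cumsum(residual))
  total <- init_offset_nm - chained
  merged <- do.call(rbind, lapply(seq_len(k), function(i) {
    s <- slices[[i]]
    s$z_nm <- s$z_nm + total[i]
    s$slice <- i
    s
  }))
  list(merged = merged, offset_nm = total, residual_nm = residual,
       chained_residual_nm = chained)
}
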