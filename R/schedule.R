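#' Interleaved acquisition schedule
#'
#' Builds the per-frame role sequence of an acquisition: single-molecule
#' (sm) frames interleaved with fiducial frames every `fiducial_period`
#' frames and reactivation frames every `reactivation_period` frames after
#' `reactivation_start` frames have elapsed. Counting is 1-based within each
#' slice for the fiducial interleave (frames 20, 40, ... at the default
#' period) and global for reactivation; when both fall on the same frame the
#' fiducial role wins.
#'
#' @param slices `data.frame(slice, sheet_z_um, focal_z_um)` from
#'   [scan_positions()], or NULL for a single slice at 0.
#' @param frames_per_slice Frames acquired in each slice.
#' @param fiducial_period Fiducial interleave period in frames (>= 1;
#'   `Inf` disables).
#' @param reactivation_period Reactivation period in frames (`Inf` disables).
#' @param reactivation_start Global frame index after which reactivation
#'   frames begin.
#' @return An `acquisition_schedule`: `data.frame(frame, slice, role,
#'   sheet_z_um, focal_z_um)` with `role` in `{"sm", "fiducial",
#'   "reactivation"}`.
#' @export
acquisition_schedule <- function(slices = NULL, frames_per_slice = 1000,
                                 fiducial_period = 20,
                                 reactivation_period = 100,
                                 reactivation_start = 10000) {
  stopifnot(frames_per_slice >= 1, fiducial_period >= 1,
            reactivation_period >= 1)
  if (is.null(slices))
    slices <- data.frame(slice = 1L, sheet_z_um = 0, focal_z_um = 0)
  n_total <- nrow(slices) * frames_per_slice
  frame <- seq_len(n_total)
  slice_idx <- rep(slices$slice, each = frames_per_slice)
  in_slice <- rep(seq_len(frames_per_slice), nrow(slices))
  role <- rep("sm", n_total)
  if (is.finite(reactivation_period))
    role[frame > reactivation_start &
           frame %% reactivation_period == 0] <- "reactivation"
  if (is.finite(fiducial_period))
    role[in_slice %% fiducial_period == 0] <- "fiducial"
  out <- data.frame(
    frame = frame, slice = slice_idx, role = role,
    sheet_z_um = rep(slices$sheet_z_um, each = frames_per_slice),
    focal_z_um = rep(slices$focal_z_um, each = frames_per_slice))
  class(out) <- c("acquisition_schedule", "data.frame")
  out
}

#' Three-state fluorophore blinking model
#'
#' Emitters cycle between an emitting on state and a dark off state and can
#' bleach irreversibly. Rates are continuous-time; per-frame transition
#' probabilities are `1 - exp(-rate * exposure)`. A reactivation frame
#' multiplies the off -> on rate by `reactivation_boost` for that frame,
#' mimicking 405 nm reactivation of dye molecules shelved in the dark state.
#'
#' @param k_off On -> off rate, 1/s.
#' @param k_on Off -> on rate, 1/s.
#' @param k_bleach Bleach rate (from on), 1/s.
#' @param initial_dark Fraction of emitters starting in the dark state
#'   (a large initial dark fraction keeps the active set sparse, as needed
#'   for a large-footprint PSF).
#' @param reactivation_boost Multiplier on `k_on` during reactivation frames.
#' @return A `blink_model` object.
#' @export
blink_model <- function(k_off = 10, k_on = 0.05, k_bleach = 0.2,
                        initial_dark = 0.9, reactivation_boost = 20) {
  stopifnot(k_off >= 0, k_on >= 0, k_bleach >= 0,
            initial_dark >= 0, initial_dark <= 1, reactivation_boost >= 1)
  structure(list(k_off = k_off, k_on = k_on, k_bleach = k_bleach,
                 initial_dark = initial_dark,
                 reactivation_boost = reactivation_boost),
            class = "blink_model")
}

#' Slow 3D stage drift model
#'
#' Either a per-axis random walk (Gaussian steps) or a linear ramp.
#'
#' @param kind `"random_walk"` or `"linear"`.
#' @param rate_nm Per-axis scale: random-walk step sd in nm/frame, or linear
#'   slope in nm/frame. Length-3 vectors give per-axis values.
#' @return A `drift_model` object.
#' @export
drift_model <- function(kind = c("random_walk", "linear", "none"),
                        rate_nm = 0.5) {
  kind <- match.arg(kind)
  structure(list(kind = kind, rate_nm = rep_len(rate_nm, 3)),
            class = "drift_model")
}

#' Realize a drift trajectory
#'
#' @param model A [drift_model()].
#' @param n_frames Number of frames.
#' @return `n_frames` x 3 matrix of cumulative (dx, dy, dz) in nm, starting
#'   at zero drift on frame 1.
#' @export
realize_drift <- function(model, n_frames) {
  if (model$kind == "none" || all(model$rate_nm == 0))
    return(matrix(0, n_frames, 3, dimnames = list(NULL, c("dx", "dy", "dz"))))
  d <- sapply(1:3, function(a) {
    if (model$kind == "linear") (seq_len(n_frames) - 1) * model$rate_nm[a]
    else cumsum(c(0, stats::rnorm(n_frames - 1, 0, model$rate_nm[a])))
  })
  colnames(d) <- c("dx", "dy", "dz")
  d
}
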