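test_that("feedback law and closed-loop sawtooth bound", {
  expect_equal(live_axial_feedback(120, 120), 0)
  expect_equal(live_axial_feedback(150, 120), 30)
  # linear drift at 0.5 nm/frame, feedback every 20 frames: residual is a
  # sawtooth bounded by period x rate once the loop is closed
  d <- (seq_len(1000) - 1) * 0.5
  fb <- simulate_axial_feedback(d, period = 20, latency = 1,
                                setpoint_nm = 0)
  expect_lte(max(abs(fb$residual_nm)), 20 * 0.5 + 1e-9)
  # sawtooth amplitude equals the drift accumulated per interleave period
  settled <- fb$residual_nm[fb$frame > 40]
  expect_equal(max(settled) - min(settled), 20 * 0.5, tolerance = 0.11)
  # dropout holds the last correction
  d2 <- d; d2[40] <- NA
  fb2 <- simulate_axial_feedback(d2, period = 20, setpoint_nm = 0)
  expect_equal(fb2$correction_nm[41], fb2$correction_nm[39])
})

test_that("drift correction with the true trace restores positions", {
  set.seed(10)
  n <- 400
  drift <- apply(matrix(rnorm(n * 3, 0, 2), n, 3), 2, cumsum)
  locs <- data.frame(frame = sample(n, 200, replace = TRUE))
  locs$x_nm <- 100 + drift[locs$frame, 1]
  locs$y_nm <- -50 + drift[locs$frame, 2]
  locs$z_nm <- 400 + drift[locs$frame, 3]
  trace <- data.frame(frame = seq_len(n), dx_nm = drift[, 1],
                      dy_nm = drift[, 2], dz_nm = drift[, 3])
  out <- apply_drift_correction(locs, trace)
  expect_equal(out$x_nm, rep(100, 200))
  expect_equal(out$z_nm, rep(400, 200))
  # zero trace is the identity
  z0 <- trace; z0$dx_nm <- z0$dy_nm <- z0$dz_nm <- 0
  expect_equal(apply_drift_correction(locs, z0)$x_nm, locs$x_nm)
  # re-application is flagged
  expect_warning(apply_drift_correction(out, trace), "already")
})

test_that("linear drift sampled every 20 frames interpolates exactly", {
  n <- 200
  drift <- cbind(0.5 * (seq_len(n) - 1), -0.2 * (seq_len(n) - 1),
                 0.1 * (seq_len(n) - 1))
  # a fiducial track sampled every 20 frames
  fr <- seq(20, n, by = 20)
  track <- data.frame(frame = fr, x_nm = 10 + drift[fr, 1],
                      y_nm = drift[fr, 2], z_nm = drift[fr, 3],
                      quality = 1, ok = TRUE)
  trace <- fiducial_drift_trace(track, seq_len(n))
  # linear interpolation of a linear drift is exact inside the sampled span
  inside <- trace$frame >= 20 & trace$frame <= 180
  expect_equal(trace$dx_nm[inside], drift[inside, 1] - drift[20, 1],
               tolerance = 1e-9)
})

test_that("multiple beads combine by inverse-variance weighting", {
  n <- 100
  fr <- seq(10, n, by = 10)
  clean <- data.frame(frame = fr, x_nm = fr * 0.3, y_nm = 0, z_nm = 0,
                      quality = 1, ok = TRUE)
  set.seed(11)
  noisy <- data.frame(frame = fr, x_nm = fr * 0.3 + rnorm(length(fr), 0, 40),
                      y_nm = 0, z_nm = 0, quality = 1, ok = TRUE)
  tr <- fiducial_drift_trace(list(clean, noisy), seq_len(n))
  # the clean bead dominates: the combined trace stays near the true line
  truth <- (seq_len(n) - 10) * 0.3
  inside <- seq_len(n) >= 10
  expect_lt(max(abs(tr$dx_nm[inside] - truth[inside])), 10)
})

test_that("stitching recovers injected residual offsets", {
  set.seed(3)
  z <- runif(4000, 0, 3000)   # featureful overlap needs structure: add bands
  z <- c(z, rnorm(2000, 1200, 60), rnorm(2000, 2000, 60))
  sA <- data.frame(z_nm = z[z < 2600], x_nm = 0, y_nm = 0)
  sB <- data.frame(z_nm = z[z > 600] - 1000 + 37, x_nm = 0, y_nm = 0)
  st <- stitch_slices(list(sA, sB), nominal_offset_nm = c(0, 1000),
                      bin_nm = 10)
  expect_equal(st$residual_nm, 37, tolerance = 5)
  # corrected merge aligns the two bands
  expect_equal(st$offset_nm[2], 1000 - st$residual_nm)
  # zero injected residual recovers ~0
  sB0 <- data.frame(z_nm = z[z > 600] - 1000, x_nm = 0, y_nm = 0)
  st0 <- stitch_slices(list(sA, sB0), nominal_offset_nm = c(0, 1000),
                       bin_nm = 10)
  expect_lt(abs(st0$residual_nm), 5)
  # three slices: chained offset is the sum of pair residuals
  sC <- data.frame(z_nm = z[z > 1600] - 2000 + 37 + 21, x_nm = 0, y_nm = 0)
  st3 <- stitch_slices(list(sA, sB, sC), nominal_offset_nm = c(0, 1000, 2000))
  expect_equal(st3$chained_residual_nm[3],
               st3$residual_nm[1] + st3$residual_nm[2])
  expect_equal(st3$chained_residual_nm[3], 58, tolerance = 8)
})

test_that("xyz stitching aligns a shell whose z marginal is flat", {
  ph <- make_phantom("lamina_shell", center_um = c(0, 0, 2), radius_um = 1.2,
                     thickness_nm = 80, density_um2 = 400, seed = 13)
  sA <- ph[ph$z_nm < 3200, ]; sA$z_nm <- sA$z_nm
  sB <- ph[ph$z_nm > 800, ];  sB$z_nm <- sB$z_nm - 1000 + 53
  st <- stitch_slices(list(sA, sB), nominal_offset_nm = c(0, 1000),
                      method = "xyz", bin_nm = 10, bin_xy_nm = 100)
  expect_equal(st$residual_nm, 53, tolerance = 8)
})

test_that("empty overlap falls back to the initialization offset", {
  sA <- data.frame(z_nm = runif(50, 0, 400), x_nm = 0, y_nm = 0)
  sB <- data.frame(z_nm = runif(50, 1600, 2000) - 1800, x_nm = 0, y_nm = 0)
  expect_warning(
    st <- stitch_slices(list(sA, sB), nominal_offset_nm = c(0, 1800)),
    "empty overlap")
  expect_equal(st$offset_nm, c(0, 1800))
})
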