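test_that("phantom generators sample the requested surfaces", {
  # shell: count within Poisson bounds of area x density, radii correct
  ph <- make_phantom("lamina_shell", center_um = c(1, -1, 5), radius_um = 5,
                     density_um2 = 10, thickness_nm = 0, seed = 1)
  lambda <- 4 * pi * 25 * 10
  expect_gt(nrow(ph), lambda - 5 * sqrt(lambda))
  expect_lt(nrow(ph), lambda + 5 * sqrt(lambda))
  r <- sqrt((ph$x_nm - 1000)^2 + (ph$y_nm + 1000)^2 + (ph$z_nm - 5000)^2)
  expect_equal(range(r), c(5000, 5000), tolerance = 1e-9)
  # cylinder: radial distance from the axis within the label thickness
  cy <- make_phantom("mito_cylinder", radius_um = 0.15, length_um = 3,
                     axis = c(0, 1, 0), thickness_nm = 40,
                     density_um2 = 200, seed = 2)
  rad <- sqrt(cy$x_nm^2 + cy$z_nm^2)
  expect_equal(median(rad), 150, tolerance = 0.05)
  expect_gt(sd(rad), 5)   # jittered by the label shell
  expect_lt(max(abs(rad - 150)), 5 * 40 / 2.355)
  # determinism
  ph2 <- make_phantom("lamina_shell", center_um = c(1, -1, 5), radius_um = 5,
                      density_um2 = 10, thickness_nm = 0, seed = 1)
  expect_identical(ph, ph2)
  expect_error(make_phantom("lamina_shell", radius_um = 0), "degenerate")
})

test_that("acquisition schedule interleaves roles with documented phasing", {
  sched <- acquisition_schedule(frames_per_slice = 250, fiducial_period = 20,
                                reactivation_period = 100,
                                reactivation_start = 150)
  expect_equal(which(sched$role == "fiducial"), seq(20, 250, by = 20))
  # reactivation every 100th after frame 150, unless a fiducial frame wins
  expect_true(all(sched$role[200] == "fiducial"))  # 200 is both; fiducial wins
  expect_false("reactivation" %in% sched$role[1:150])
  sched2 <- acquisition_schedule(frames_per_slice = 350,
                                 fiducial_period = Inf,
                                 reactivation_period = 100,
                                 reactivation_start = 150)
  expect_equal(which(sched2$role == "reactivation"), c(200, 300))
})

test_that("dark calibration recovers the offset to the standard error", {
  cam <- camera_model(offset = 100, read_noise_e = 30, conversion = 10)
  set.seed(7)
  dark <- simulate_dark_frames(cam, dims = c(24, 24), n_frames = 300)
  m <- dark_calibrate(dark)
  # constant-offset map: per-pixel mean within 5 standard errors
  se <- (30 / 10) / sqrt(300)
  expect_gt(mean(abs(m - 100) < 5 * se), 0.99)
  # subtracting the set's own mean leaves ~zero residual
  expect_equal(mean(sweep(dark, 1:2, m)), 0, tolerance = 1e-9)
  expect_error(dark_calibrate(dark[, , 1, drop = FALSE]), "at least 2")
})

test_that("counts-to-photons inverts the mean EM-CCD transfer", {
  cam <- camera_model(em_gain = 186, conversion = 10, offset = 100,
                      quantum_efficiency = 1, read_noise_e = 5)
  expect_equal(counts_to_photons(186 / 10 * 3, cam), 3)
  cam1 <- camera_model(em_gain = 1, conversion = 1, offset = 0,
                       quantum_efficiency = 1)
  expect_equal(counts_to_photons(42, cam1), 42)
  # Monte-Carlo: mean photon estimate of a Poisson source within 2%
  set.seed(8)
  lambda <- 1000
  frames <- replicate(3000, {
    counts <- apply_camera_noise(matrix(lambda, 1, 1), cam)
    counts_to_photons(subtract_dark(counts, 100), cam)
  })
  expect_equal(mean(frames), lambda, tolerance = 0.02)
})

test_that("streams are deterministic and photon-budget exact", {
  cfg <- fx("cfg")
  dh <- fx("dh_small")
  ph <- make_phantom("points", positions = data.frame(
    x_nm = c(-1200, 1000), y_nm = c(800, -900), z_nm = c(-300, 400)))
  sched <- acquisition_schedule(frames_per_slice = 6, fiducial_period = Inf,
                                reactivation_period = Inf)
  still <- blink_model(k_off = 0, k_on = 0, k_bleach = 0, initial_dark = 0)
  args <- list(phantom = ph, schedule = sched,
               illumination = illumination_field("epi"),
               masks = list(sm = fx("dh_opt")), config = cfg,
               camera = camera_model(),
               blink = still, fov = list(nx = 48, ny = 48, pixel_nm = 160),
               roi_px = list(sm = 41, fiducial = 41),
               photon_rate = 6e4, background = 5, seed = 123)
  s1 <- do.call(simulate_stream, args)
  s2 <- do.call(simulate_stream, args)
  expect_identical(s1$frames, s2$frames)
  expect_identical(s1$truth, s2$truth)
  # noiseless photon budget: the logged expected photons follow
  # brightness x exposure x illumination intensity exactly
  args["camera"] <- list(NULL)
  s0 <- do.call(simulate_stream, args)
  t1 <- s0$truth[s0$truth$frame == 1, ]
  expect_equal(t1$photons, rep(6e4 * 0.05, 2))
  # the frame carries that budget up to the documented render-ROI cutoff
  total <- sum(s0$frames[, , 1])
  expect_lt(total, 5 * 48 * 48 + sum(t1$photons) + 1e-6)
  expect_gt(total, 5 * 48 * 48 + 0.9 * sum(t1$photons))
  # ground-truth log re-renders the noiseless frame bit-for-bit
  expect_identical(re_render_frame(s0, 3), s0$frames[, , 3])
})

test_that("empty and edge streams behave", {
  sched <- acquisition_schedule(frames_per_slice = 3, fiducial_period = Inf,
                                reactivation_period = Inf)
  s <- simulate_stream(
    make_phantom("points",
                 positions = data.frame(x_nm = numeric(), y_nm = numeric(),
                                        z_nm = numeric())),
    sched, illumination_field("epi"), masks = list(sm = fx("dh_small")),
    config = fx("cfg"), camera = camera_model(offset = 100),
    fov = list(nx = 24, ny = 24, pixel_nm = 160), background = 0, seed = 5)
  # offset plus read noise only
  expect_equal(mean(s$frames), 100, tolerance = 0.01)
  # emitter far outside the field is skipped and logged as clipped
  s2 <- simulate_stream(
    make_phantom("points",
                 positions = data.frame(x_nm = 50000, y_nm = 0, z_nm = 0)),
    sched, illumination_field("epi"), masks = list(sm = fx("dh_small")),
    config = fx("cfg"), camera = NULL,
    blink = blink_model(k_off = 0, k_on = 0, k_bleach = 0, initial_dark = 0),
    fov = list(nx = 24, ny = 24, pixel_nm = 160), background = 0, seed = 5)
  expect_true(all(s2$truth$clipped))
  expect_equal(sum(s2$frames), 0)
})

test_that("blinking follows the three-state rates and reactivation boost", {
  ph <- make_phantom("points", positions = data.frame(
    x_nm = rep(0, 400), y_nm = rep(0, 400), z_nm = rep(0, 400)))
  sched <- acquisition_schedule(frames_per_slice = 40,
                                fiducial_period = Inf,
                                reactivation_period = Inf)
  # all start dark with k_on = 0: nothing ever emits
  s <- simulate_stream(ph, sched, illumination_field("epi"),
                       masks = list(sm = fx("dh_small")), config = fx("cfg"),
                       camera = NULL,
                       blink = blink_model(k_on = 0, initial_dark = 1),
                       fov = list(nx = 24, ny = 24, pixel_nm = 160),
                       background = 0, seed = 6)
  expect_equal(nrow(s$truth), 0)
  # with reactivation frames, the dark pool lights up much faster
  mk <- function(react_period) {
    sched <- acquisition_schedule(frames_per_slice = 40,
                                  fiducial_period = Inf,
                                  reactivation_period = react_period,
                                  reactivation_start = 0)
    s <- simulate_stream(ph, sched, illumination_field("epi"),
                         masks = list(sm = fx("dh_small")),
                         config = fx("cfg"), camera = NULL,
                         blink = blink_model(k_on = 0.05, k_off = 10,
                                             k_bleach = 0, initial_dark = 1,
                                             reactivation_boost = 20),
                         fov = list(nx = 24, ny = 24, pixel_nm = 160),
                         background = 0, seed = 7)
    nrow(s$truth)
  }
  expect_gt(mk(2), 3 * mk(Inf))
})
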