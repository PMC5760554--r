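test_that("candidate detection finds isolated double-helix emitters", {
  cfg <- fx("cfg")
  dh <- fx("dh_opt")
  cal <- fx("dh_cal")
  sep0 <- stats::approx(cal$z_nm, cal$separation_nm, 0)$y
  blank <- matrix(5, 48, 48)
  expect_equal(nrow(detect_candidates(blank, sep0, 150, 160)), 0)
  fov <- list(nx = 48, ny = 48, pixel_nm = 160)
  put <- function(img, x, y, z, n = 3000)
    helixsheet:::add_emitter_image(img, dh, cfg, fov, x, y, z, n, 23)$img
  set.seed(31)
  one <- put(matrix(0, 48, 48), 480, -320, 200) + 5
  one <- matrix(rpois(48 * 48, one), 48, 48)
  cand <- detect_candidates(one, sep0, 150, 160)
  expect_equal(nrow(cand), 1)
  expect_lt(abs(cand$x_px - (24.5 + 3)), 1.5)
  expect_lt(abs(cand$y_px - (24.5 - 2)), 1.5)
  # two well-separated emitters give two candidates
  two <- put(put(matrix(0, 48, 48), -1800, -1800, 0), 1800, 1800, -300) + 5
  two <- matrix(rpois(48 * 48, two), 48, 48)
  expect_equal(nrow(detect_candidates(two, sep0, 150, 160)), 2)
})

test_that("double-Gaussian fit recovers noiseless parameters to < 0.01 px", {
  xx <- matrix(1:21, 21, 21, byrow = TRUE)
  yy <- matrix(1:21, 21, 21)
  g <- function(x0, y0, a, s) a * exp(-((xx - x0)^2 + (yy - y0)^2) / (2 * s^2))
  roi <- g(8.3, 12.1, 900, 1.3) + g(13.7, 9.9, 800, 1.3) + 10
  ft <- fit_double_gaussian(roi, pixel_nm = 160)
  expect_true(ft$converged)
  expect_false(ft$rejected)
  centers <- ft$centers[order(ft$centers[, "x"]), ]
  expect_equal(unname(centers[1, ]), c(8.3, 12.1), tolerance = 1e-3)
  expect_equal(unname(centers[2, ]), c(13.7, 9.9), tolerance = 1e-3)
  expect_equal(ft$bg, 10, tolerance = 1e-3)
  expect_equal(ft$sigma_px, 1.3, tolerance = 1e-3)
  # a single-Gaussian ROI collapses the lobes and is rejected
  ft1 <- fit_double_gaussian(g(11, 11, 1000, 1.4) + 5, pixel_nm = 160)
  expect_true(ft1$rejected)
  # mirror symmetry: mirrored ROI gives mirrored centers, same residual
  ftm <- fit_double_gaussian(roi[, 21:1], pixel_nm = 160)
  cm <- ftm$centers[order(ftm$centers[, "x"]), ]
  expect_equal(unname(cm[, "x"]), 22 - unname(centers[2:1, "x"]),
               tolerance = 1e-3)
  expect_equal(ftm$residual, ft$residual, tolerance = 1e-6)
})

test_that("bead-stack calibration spans the working range and interpolates", {
  cal <- fx("dh_cal")
  expect_gte(diff(cal$valid_range_nm), 1800)
  expect_true(all(diff(cal$angle_deg) > 0) || all(diff(cal$angle_deg) < 0))
  expect_lt(diff(range(cal$angle_deg)), 180)
  # decimating the stack 2x changes the inverted z by < 5 nm
  st2 <- psf_stack(fx("dh_opt"), seq(-1200, 1200, by = 200), fx("cfg"),
                   roi_px = 25)
  cal2 <- calibrate_dh(st2)
  probe <- seq(-900, 900, by = 150)
  ang <- stats::approx(cal$z_nm, cal$angle_deg, probe)$y + cal$raw_ref_deg
  z1 <- z_from_angle(cal, ang)
  z2 <- z_from_angle(cal2, ang)
  expect_lt(max(abs(z1 - z2)), 5)
  # reversed stack order gives the same calibration
  st_rev <- list(images = st2$images[, , 13:1], z_nm = rev(st2$z_nm),
                 pixel_nm = st2$pixel_nm, kind = st2$kind)
  cal_rev <- calibrate_dh(st_rev)
  expect_equal(cal_rev$angle_deg, cal2$angle_deg, tolerance = 1e-6)
})

test_that("angle inversion respects the calibration convention", {
  cal <- fx("dh_cal")
  # the z = 0 reference angle inverts to z = 0
  expect_equal(z_from_angle(cal, cal$raw_ref_deg), 0, tolerance = 1)
  # out-of-range angles are rejected as NA
  expect_true(is.na(z_from_angle(cal, cal$raw_ref_deg +
                                   max(cal$angle_deg) + 20)))
})

test_that("render-fit-invert round trip is accurate; midpoint is stable", {
  cfg <- fx("cfg")
  dh <- fx("dh_opt")
  cal <- fx("dh_cal")
  for (zt in c(-700, 0, 500)) {
    roi <- render_emitter(dh, zt, cfg, dx_nm = 37, dy_nm = -53,
                          roi_px = 25) * 3000 + 10
    loc <- localize_roi(roi, cal)
    expect_true(loc$ok)
    expect_equal(loc$z_nm, zt, tolerance = 10)
    expect_equal(loc$x_nm, 37, tolerance = 5)
    expect_equal(loc$y_nm, -53, tolerance = 5)
  }
  # swapping lobe labels leaves the localization unchanged: the fit is
  # invariant under a 180-degree relabeling of the initialization angle
  roi <- render_emitter(dh, 300, cfg, roi_px = 25) * 3000 + 10
  f1 <- fit_double_gaussian(roi, init = list(angle_deg = 110), pixel_nm = 160)
  f2 <- fit_double_gaussian(roi, init = list(angle_deg = 290), pixel_nm = 160)
  expect_equal(f1$mx_px, f2$mx_px, tolerance = 1e-4)
  expect_equal(f1$angle_deg, f2$angle_deg, tolerance = 1e-4)
})

test_that("fitting is equivariant under whole-pixel translation", {
  cfg <- fx("cfg")
  dh <- fx("dh_opt")
  fov <- list(nx = 40, ny = 40, pixel_nm = 160)
  img <- helixsheet:::add_emitter_image(matrix(0, 40, 40), dh, cfg, fov,
                                        -160, 320, 250, 3000, 25)$img + 3
  f1 <- fit_double_gaussian(img[6:30, 6:30], pixel_nm = 160)
  f2 <- fit_double_gaussian(img[8:32, 8:32], pixel_nm = 160)
  expect_equal(f1$mx_px - f2$mx_px, 2, tolerance = 1e-3)
  expect_equal(f1$my_px - f2$my_px, 2, tolerance = 1e-3)
  expect_equal(f1$angle_deg, f2$angle_deg, tolerance = 0.01)
})

test_that("quality filtering drops documented failure modes monotonically", {
  base <- data.frame(x_nm = 0, y_nm = 0, z_nm = 100, photons = 2000,
                     background = 5, angle_deg = 10, separation_nm = 900,
                     asymmetry = 1.2, residual = 1.5, frame = 1, slice = 1,
                     ok = TRUE, reason = NA_character_)
  locs <- do.call(rbind, replicate(6, base, simplify = FALSE))
  locs$asymmetry[2] <- 10      # 10:1 lobe imbalance
  locs$residual[3] <- 9
  locs$photons[4] <- 50
  locs$z_nm[5] <- 9000
  locs$ok[6] <- FALSE
  kept <- filter_localizations(locs, dh_filter_policy(
    z_range_nm = c(-1200, 1200)))
  expect_equal(nrow(kept), 1)
  dropped <- attr(kept, "dropped")
  expect_setequal(dropped$reason,
                  c("asymmetry", "residual", "photons", "z range",
                    "fit rejected"))
  # empty policy is the identity
  expect_equal(nrow(filter_localizations(locs, list())), 6)
  # survivor count is monotone non-increasing as a threshold tightens
  counts <- vapply(c(20, 5, 2, 1.1),
                   function(a) nrow(filter_localizations(
                     locs, dh_filter_policy(max_asymmetry = a,
                                            z_range_nm = c(-1200, 1200)))),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("empirical precision detrends drift and obeys photon scaling", {
  same <- data.frame(x_nm = rep(1, 30), y_nm = 2, z_nm = 3, frame = 1:30)
  expect_equal(unname(empirical_precision(same)), c(0, 0, 0))
  expect_error(empirical_precision(same[1:5, ]), "at least")
  # linear drift is removed before the sd
  dr <- same
  dr$x_nm <- dr$x_nm + dr$frame * 5
  expect_equal(unname(empirical_precision(dr)["x"]), 0, tolerance = 1e-9)
  # quadrupling photons halves the scatter (shot-noise scaling)
  cfg <- fx("cfg")
  dh <- fx("dh_opt")
  cal <- fx("dh_cal")
  set.seed(33)
  run <- function(n_phot) {
    roi0 <- render_emitter(dh, 200, cfg, dx_nm = 20, dy_nm = 10,
                           roi_px = 25) * n_phot + 10
    locs <- do.call(rbind, lapply(1:60, function(i) {
      roi <- matrix(stats::rpois(625, roi0), 25, 25)
      localize_roi(roi, cal, mask = dh)
    }))
    empirical_precision(locs[locs$ok, ])
  }
  s1 <- run(1500); s4 <- run(6000)
  expect_equal(unname(s1 / s4), c(2, 2, 2), tolerance = 0.45)
})
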