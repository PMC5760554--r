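test_that("Fourier-plane diameter follows the Abbe-sine relation", {
  expect_equal(round(fourier_plane_diameter(150, na = 1.4,
                                            magnification = 100), 1), 4.2)
  expect_equal(round(fourier_plane_diameter(90, na = 1.4,
                                            magnification = 100), 1), 2.5)
  # zero-aperture limit
  expect_equal(fourier_plane_diameter(100, na = 1e-9, magnification = 100),
               2e-9, tolerance = 1e-6)
  # degenerate Abbe-sine geometry rejected
  expect_error(fourier_plane_diameter(100, na = 120, magnification = 100),
               "degenerate")
  expect_error(optical_config(numerical_aperture = 1.6),
               "immersion")
})

test_that("optical config derives the effective pixel and validates inputs", {
  cfg <- optical_config()
  expect_equal(cfg$effective_pixel_nm,
               cfg$camera_pixel_pitch * 1000 / cfg$magnification)
  expect_error(pupil_grid(100, 64))  # side must be >= 2x aperture diameter
})

test_that("clear mask has zero phase and a unit-sum, Airy-limited focal PSF", {
  clear <- fx("clear")
  expect_equal(max(abs(clear$phase)), 0)
  im <- psf_at(clear, 0, fx("cfg"))
  expect_equal(sum(im), 1, tolerance = 1e-6)
  # first radial minimum within 5% of the Airy radius 0.61 lambda / NA
  px <- attr(im, "pixel_nm")
  n <- nrow(im)
  c0 <- n / 2 + 1
  r <- sqrt((row(im) - c0)^2 + (col(im) - c0)^2) * px
  prof <- tapply(as.numeric(im), round(r / 5), mean)
  rr <- as.numeric(names(prof)) * 5
  i_min <- which(diff(sign(diff(prof))) > 0)[1] + 1
  airy <- 0.61 * fx("cfg")$emission_wavelength / fx("cfg")$numerical_aperture
  expect_lt(abs(rr[i_min] - airy) / airy, 0.05)
})

test_that("PSF energy is conserved across the nominal axial range", {
  dh <- fx("dh")
  sums <- vapply(seq(-1000, 1000, by = 500),
                 function(z) sum(psf_at(dh, z, fx("cfg"))), numeric(1))
  expect_lt(diff(range(sums)) / mean(sums), 0.01)
  # the clipping guard trips when the PSF outgrows the field
  tp <- build_mask("tetrapod", 10, fx("grid_small"), fx("cfg"))
  expect_error(psf_at(tp, 60000, fx("cfg"), pad = 1), "clipped")
})

test_that("double-helix PSF shows two dominant lobes that rotate with z", {
  dh <- fx("dh")
  cfg <- fx("cfg")
  im0 <- render_emitter(dh, 0, cfg, roi_px = 23)
  lb <- helixsheet:::find_lobe_pair(im0)
  # two near-equal dominant maxima
  expect_gt(lb$i2 / lb$i1, 0.8)
  # opposite rotation on opposite sides of focus
  curve <- dh_angle_curve(dh, c(-600, 0, 600), cfg)
  expect_lt(curve$angle_deg[1], 0)
  expect_gt(curve$angle_deg[3], 0)
  expect_equal(curve$angle_deg[2], 0)
})

test_that("double-helix angle-z curve is strictly monotone, < 180 degrees", {
  curve <- dh_angle_curve(fx("dh"), seq(-1000, 1000, by = 100), fx("cfg"))
  expect_true(attr(curve, "monotone"))
  expect_lt(diff(range(curve$angle_deg)), 180)
  # reversing the z grid yields the same (z, angle) pairs
  rev_curve <- dh_angle_curve(fx("dh"), seq(1000, -1000, by = -100),
                              fx("cfg"))
  expect_equal(rev_curve$angle_deg[order(rev_curve$z_nm)],
               curve$angle_deg[order(curve$z_nm)], tolerance = 1e-6)
})

test_that("tetrapod footprint spreads with defocus and the recipe is smooth", {
  cfg <- fx("cfg")
  tp <- build_mask("tetrapod", 6, fx("grid"), cfg)
  footprint <- function(z) {
    im <- render_emitter(tp, z, cfg, roi_px = 51, pixel_nm = 160)
    c0 <- 26
    sqrt(sum(im * ((row(im) - c0)^2 + (col(im) - c0)^2)) / sum(im))
  }
  expect_gt(footprint(3000), footprint(0))
  expect_gt(footprint(-3000), footprint(0))
  # deformable-mirror-realizable: bounded finite-difference gradient
  g <- fx("grid")
  inner <- g$rho <= 0.95
  dphase <- abs(diff(tp$phase))
  expect_lt(max(dphase[inner[-1, ] & inner[-nrow(inner), ]]), pi)
  expect_error(build_mask("tetrapod", 4, fx("grid"), cfg), "6 and 10")
})

test_that("render_emitter places sub-pixel offsets exactly", {
  cfg <- fx("cfg")
  roi <- render_emitter(fx("clear"), 0, cfg, dx_nm = 80, dy_nm = -40,
                        roi_px = 21)
  cx <- sum(col(roi) * roi) / sum(roi)
  cy <- sum(row(roi) * roi) / sum(roi)
  expect_equal(cx, 11 + 80 / 160, tolerance = 0.01)
  expect_equal(cy, 11 - 40 / 160, tolerance = 0.01)
})

test_that("CRLB scales as 1/sqrt(N) and flags uninformative axes", {
  dh <- fx("dh_small")
  cfg <- fx("cfg")
  b1 <- crlb(dh, 1000, 0, 0, cfg)
  b4 <- crlb(dh, 4000, 0, 0, cfg)
  expect_equal(unname(b1 / b4), c(2, 2, 2), tolerance = 0.01)
  # clear aperture at focus: no first-order z information
  bc <- crlb(fx("clear"), 3000, 0, 0, cfg)
  expect_true(is.infinite(bc["z"]) || bc["z"] > 100 * bc["x"])
  # DH z-bound roughly uniform (within 2x) across the 2 um range
  bz <- vapply(seq(-1000, 1000, by = 250),
               function(z) crlb(dh, 3000, 0, z, cfg)[["z"]], numeric(1))
  expect_lt(max(bz) / min(bz), 2)
})

test_that("optimized DH mask concentrates energy into the two lobes", {
  dh0 <- fx("dh_small")
  dh1 <- fx("dh_opt")
  lobe_frac <- function(m) {
    # energy within 2.5 pixels of each lobe peak (fit-free oracle)
    im <- render_emitter(m, 0, fx("cfg"), roi_px = 25)
    lb <- helixsheet:::find_lobe_pair(im)
    near <- function(c0) (row(im) - c0[1])^2 + (col(im) - c0[2])^2 <= 2.5^2
    sum(im[near(lb$c1) | near(lb$c2)])
  }
  expect_gt(lobe_frac(dh1), lobe_frac(dh0) + 0.15)
  curve <- dh_angle_curve(dh1, seq(-1000, 1000, by = 200), fx("cfg"))
  expect_true(attr(curve, "monotone"))
})

test_that("PSF stacks survive a TIFF round trip", {
  st <- psf_stack(fx("dh_small"), c(-500, 0, 500), fx("cfg"), roi_px = 15)
  path <- tempfile(fileext = ".tif")
  write_psf_stack(st, path, config = fx("cfg"))
  st2 <- read_psf_stack(path)
  expect_equal(st2$z_nm, st$z_nm)
  expect_equal(st2$images, st$images, tolerance = 1e-4)
  unlink(c(path, paste0(path, ".yaml")))
})
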