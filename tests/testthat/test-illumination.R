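sheet_field <- function(center_z_um = 0, ...)
  illumination_field("sheet", sheet_params(center_z_um = center_z_um, ...))

test_that("sheet intensity follows the tilted Gaussian geometry", {
  f <- sheet_field(center_z_um = 5)
  # peak at the waist center
  expect_equal(intensity_at(f, 0, 0, 5000), 1)
  # one waist radius along the sheet normal: 1/e^2
  tau <- 10 * pi / 180
  expect_equal(intensity_at(f, 2100 * sin(tau), 0, 5000 + 2100 * cos(tau)),
               exp(-2), tolerance = 1e-9)
  # one width along y: 1/e^2
  expect_equal(intensity_at(f, 0, 19000, 5000), exp(-2), tolerance = 1e-9)
  # epi mode is z-uniform
  fe <- illumination_field("epi")
  expect_equal(intensity_at(fe, 0, 0, c(0, 5000, 10000)), rep(1, 3))
})

test_that("the 10-degree tilt displaces the intensity maximum as x tan(tilt)", {
  f <- sheet_field(center_z_um = 5)
  zg <- seq(2000, 8000, by = 2)
  zmax <- function(x_nm) zg[which.max(intensity_at(f, x_nm, 0, zg))]
  dx <- 6000
  expect_equal(zmax(-dx / 2) - zmax(dx / 2), dx * tan(10 * pi / 180),
               tolerance = 0.01)
})

test_that("sheet power is conserved along propagation", {
  f <- sheet_field(center_z_um = 5)
  tau <- 10 * pi / 180
  integral_at <- function(s_um) {
    nn <- seq(-9000, 9000, by = 10)
    x <- s_um * 1000 * cos(tau) + nn * sin(tau)
    z <- 5000 - s_um * 1000 * sin(tau) + nn * cos(tau)
    sum(intensity_at(f, x, 0, z)) * 10
  }
  vals <- vapply(c(0, 10, 20, 36), integral_at, numeric(1))
  expect_lt(diff(range(vals)) / mean(vals), 0.02)
})

test_that("sheet geometry reaches the coverslip inside the field of view", {
  # with the waist centered low in the field the tilted sheet center crosses
  # z = 0 within the field while entering the chamber above it
  sh <- sheet_params(center_z_um = 1)
  tau <- sh$tilt_deg * pi / 180
  field_x_um <- c(-50, 7.5)
  center_height <- function(x_um) sh$center_z_um - x_um * tan(tau)
  expect_lte(min(center_height(field_x_um[2]), center_height(0)), 1)
  expect_gt(center_height(field_x_um[1]), 1)  # entry side is higher
})

test_that("scan positions form an inclusive sequence paired with the focus", {
  sp <- scan_positions(0, 6, 1)
  expect_equal(nrow(sp), 7)
  expect_equal(sp$sheet_z_um, 0:6)
  expect_equal(sp$sheet_z_um, sp$focal_z_um)
  expect_equal(nrow(scan_positions(0, 0, 1)), 1)
  expect_error(scan_positions(3, 1, 1), "empty")
})

test_that("slab background: epi scales with thickness, sheet does not", {
  cfg <- optical_config()
  f_epi <- illumination_field("epi")
  expect_equal(background_rate(f_epi,
                               list(z_min_um = 0, z_max_um = 10,
                                    density_um3 = 0)), 0)
  b_epi_10 <- background_rate(f_epi, list(z_min_um = 0, z_max_um = 10,
                                          density_um3 = 1), config = cfg)
  b_epi_20 <- background_rate(f_epi, list(z_min_um = 0, z_max_um = 20,
                                          density_um3 = 1), config = cfg)
  expect_equal(b_epi_20 / b_epi_10, 2, tolerance = 0.01)
  b_sh_10 <- background_rate(sheet_field(5), list(z_min_um = 0, z_max_um = 10,
                                                  density_um3 = 1),
                             config = cfg)
  b_sh_20 <- background_rate(sheet_field(10),
                             list(z_min_um = 0, z_max_um = 20,
                                  density_um3 = 1), config = cfg)
  expect_equal(b_sh_20 / b_sh_10, 1, tolerance = 0.1)
  # the epi/sheet ratio on a 10 um slab sits in the "up to fivefold" band
  expect_gt(b_epi_10 / b_sh_10, 3)
  expect_lt(b_epi_10 / b_sh_10, 7)
})

test_that("SBR arithmetic and degenerate cases", {
  expect_equal(sbr(1000, 10, 0.3) / sbr(1000, 20, 0.3), 2)
  expect_equal(sbr(0, 10), 0)
  expect_warning(v <- sbr(100, 0), "infinite")
  expect_true(is.infinite(v))
  # improvement factor grows with slab thickness
  cfg <- optical_config()
  ratios <- vapply(c(6, 10, 16), function(t) {
    be <- background_rate(illumination_field("epi"),
                          list(z_min_um = 0, z_max_um = t, density_um3 = 1),
                          config = cfg)
    bs <- background_rate(sheet_field(t / 2),
                          list(z_min_um = 0, z_max_um = t, density_um3 = 1),
                          config = cfg)
    be / bs
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("illumination_map samples an xz cross-section", {
  m <- illumination_map(sheet_field(2), x_um = c(-5, 5), z_um = c(0, 4),
                        step_um = 0.5)
  expect_equal(dim(m), c(9, 21))
  expect_equal(max(m), intensity_at(sheet_field(2), 0, 0, 2000),
               tolerance = 0.05)
})
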