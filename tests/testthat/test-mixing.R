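# Water-mass and river-seawater mixing.

test_that("conservative quantities mix exactly linearly", {
  em <- gom_endmembers()
  st <- mix_waters(list(em$WSW, em$LSW, em$SSW), c(0.2, 0.5, 0.3), 10)
  expect_equal(st$alk, 0.2 * 2375 + 0.5 * 2200 + 0.3 * 2150)
  expect_equal(st$dic, 0.2 * 2050 + 0.5 * 2050 + 0.3 * 2000)
  expect_equal(st$salinity, 0.2 * 36.5 + 0.5 * 34 + 0.3 * 32)
})

test_that("single-endmember and 50/50 mixtures reduce correctly", {
  em <- gom_endmembers()
  st <- mix_waters(list(em$WSW), 1, 11)
  expect_equal(st$alk, 2375)
  expect_equal(st$ph, ph_from_alk_dic(2375, 2050, carb_constants(11, 36.5)))
  half <- mix_waters(list(em$WSW, em$SSW), c(0.5, 0.5), 11)
  expect_equal(half$alk, (2375 + 2150) / 2)
  expect_equal(half$dic, (2050 + 2000) / 2)
})

test_that("invalid mixing fractions raise an invalid-scenario error", {
  em <- gom_endmembers()
  expect_error(mix_waters(list(em$WSW, em$LSW), c(0.6, 0.6), 10),
               "sum to 1")
  expect_error(mix_waters(list(em$WSW, em$LSW), c(1.2, -0.2), 10),
               "\\[0, 1\\]")
})

test_that("pH rises monotonically with the Warm Slope Water fraction", {
  sw <- wsw_sweep(f_wsw = seq(0, 1, 0.1))
  for (t in unique(sw$temperature)) {
    expect_true(all(diff(sw$ph[sw$temperature == t]) > 0))
  }
  # endpoints reduce to the pure endmembers
  em <- gom_endmembers()
  expect_equal(sw$ph[sw$f_wsw == 0 & sw$temperature == 11],
               ph_from_alk_dic(2200, 2050, carb_constants(11, 34)))
  expect_equal(sw$ph[sw$f_wsw == 1 & sw$temperature == 11],
               ph_from_alk_dic(2375, 2050, carb_constants(11, 36.5)))
})

test_that("the 1960s-to-1990s WSW increase raises pH by more than 0.15", {
  sw <- wsw_sweep(f_wsw = c(0.2, 0.7), temperatures = 11)
  expect_gte(diff(sw$ph), 0.15)
})

test_that("cooling from 11 to 8 degC raises pH by less than 0.05", {
  sw <- wsw_sweep(f_wsw = c(0.2, 0.5, 0.8))
  d <- sw$ph[sw$temperature == 8] - sw$ph[sw$temperature == 11]
  expect_true(all(d > 0))
  expect_true(all(d < 0.05))
})

test_that("ternary grid covers the simplex with correct vertices", {
  res <- 5
  g <- ternary_grid(resolution = res, temperature = 11)
  expect_equal(nrow(g), choose(res + 1, 2))
  expect_true(all(abs(g$f_wsw + g$f_lsw + g$f_ssw - 1) < 1e-9))
  em <- gom_endmembers()
  v <- g[g$f_wsw == 1, ]
  expect_equal(v$ph, ph_from_alk_dic(2375, 2050, carb_constants(11, 36.5)))
  # barycentre equals the equal-parts mixture
  g3 <- ternary_grid(resolution = 4, temperature = 11)
  bary <- g3[abs(g3$f_wsw - 1 / 3) < 1e-9 & abs(g3$f_lsw - 1 / 3) < 1e-9, ]
  st <- mix_waters(list(em$WSW, em$LSW, em$SSW), rep(1 / 3, 3), 11)
  expect_equal(bary$ph, st$ph)
})

test_that("unmixed seawater sits at pH 8.0 and 5% river shifts it ~0.02", {
  r0 <- river_mix(0, river_ph = 6.6)
  expect_equal(r0$ph, 8.0, tolerance = 0.01 / 8)
  shift <- river_ph_shift(f_river = 0.05)
  expect_equal(shift$delta_ph, 0.02, tolerance = 0.01 / 0.02)
})

test_that("river DIC modes cover the published values", {
  # published pairs are the caption default
  expect_equal(suppressWarnings(river_mix(0.5, 6.6)$dic),
               0.5 * 428 + 0.5 * 2050)
  expect_equal(suppressWarnings(river_mix(0.5, 7.2)$dic),
               0.5 * 261 + 0.5 * 2050)
  # recomputed DIC at river pH 7.2 lands near the published 261
  r <- suppressWarnings(
    river_mix(1, 7.2, river_dic = "solve", river_salinity = 0.5))
  rdic <- r$dic  # pure river
  expect_equal(rdic, 261, tolerance = 0.05)
})

test_that("the between-era pH shift grows monotonically with river fraction", {
  shift <- suppressWarnings(river_ph_shift(f_river = seq(0, 0.6, 0.05)))
  expect_true(all(diff(shift$delta_ph) > 0))
})

test_that("the 0.2 shift needs well over 20% river water, at any plausible river alkalinity", {
  sens <- suppressWarnings(river_sensitivity(alk_scale = c(0.5, 1, 1.5)))
  expect_true(all(sens$f_river_threshold > 0.2))
  # scale 1 reproduces the plain sweep
  shift <- suppressWarnings(river_ph_shift())
  direct <- shift$f_river[min(which(shift$delta_ph >= 0.2))]
  expect_equal(sens$f_river_threshold[sens$alk_scale == 1], direct)
})

test_that("dilute mixtures warn below the 19 psu validity limit", {
  expect_warning(river_mix(0.6, 6.6), "19 psu")
  expect_silent(river_mix(0.05, 6.6))
})

test_that("river model validates its inputs", {
  expect_error(river_mix(0.05, river_ph = 5.5), "6, 8")
  expect_error(river_mix(-0.1, 6.6), "f_river")
})
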