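# Carbonate-system constants and solvers.

test_that("Lueker pK1 reproduces the published temperature dependence", {
  expect_equal(-log10(carb_constants(8, 32)$K1), 6.03, tolerance = 0.01 / 6)
  expect_equal(-log10(carb_constants(11, 32)$K1), 6.00, tolerance = 0.01 / 6)
})

test_that("constants obey basic thermodynamic structure", {
  cs <- carb_constants(10, 32)
  expect_true(all(unlist(cs[c("K0", "K1", "K2", "KB", "Kw", "BT")]) > 0))
  expect_gt(cs$K1, cs$K2)
  # pK1 falls as T rises at fixed S
  pk1 <- sapply(c(5, 10, 15, 20, 25), function(t) {
    -log10(carb_constants(t, 32)$K1)
  })
  expect_true(all(diff(pk1) < 0))
  # total boron proportional to salinity
  expect_equal(carb_constants(10, 35)$BT, 0.0004157)
  expect_equal(carb_constants(10, 17.5, bt_scale = 1)$BT / 0.0004157, 0.5,
               tolerance = 1e-12) |> suppressWarnings()
  expect_lt(suppressWarnings(carb_constants(10, 1e-6)$BT), 1e-10)
})

test_that("input validation and the low-salinity warning behave as stated", {
  expect_error(carb_constants(-1, 32), "temperature")
  expect_error(carb_constants(10, 0), "salinity")
  expect_error(carb_constants(10, 50), "salinity")
  expect_error(carb_constants(NaN, 32), "finite")
  expect_warning(carb_constants(10, 15), "19 psu")
  # warned, not clamped: the value is the extrapolated one
  k <- suppressWarnings(carb_constants(10, 15))
  expect_equal(k$salinity, 15)
})

test_that("pKB* averages to 8.82 over the local T range at S = 30.3", {
  expect_equal(mean(sapply(6:11, pkb_star, salinity = 30.3)), 8.82,
               tolerance = 0.02 / 8.82)
  expect_equal(pkb_star(10, 30.3), 8.805782, tolerance = 1e-6)
  pkb <- sapply(c(6, 8, 10, 12), pkb_star, salinity = 30.3)
  expect_true(all(diff(pkb) < 0))
})

test_that("pH solver matches the brute-force scan oracle", {
  k <- carb_constants(11, 34.5)
  expect_equal(ph_from_alk_dic(2235, 2050, k),
               ph_scan_oracle(2235, 2050, k), tolerance = 1e-4)
  expect_equal(ph_from_alk_dic(2235, 2050, k), 8.0495, tolerance = 1e-4)
  # the offshore Gulf of Maine reference water sits at pH 8.0
  expect_equal(ph_from_alk_dic(2200, 2050, carb_constants(10, 33)), 8.0,
               tolerance = 0.01 / 8)
})

test_that("solved state satisfies the alkalinity balance to < 0.01 umol/kg", {
  set.seed(42)
  for (i in 1:20) {
    t <- runif(1, 2, 25); s <- runif(1, 20, 40)
    alk <- runif(1, 2000, 2450); dic <- runif(1, 1800, alk - 50)
    k <- carb_constants(t, s)
    ph <- ph_from_alk_dic(alk, dic, k)
    expect_lt(abs(alk_from_ph_dic(ph, dic, k) - alk), 0.01)
  }
})

test_that("pH is monotone in ALK (rising) and DIC (falling)", {
  k <- carb_constants(10, 32)
  ph_alk <- sapply(seq(2100, 2400, 50), ph_from_alk_dic, dic = 2000,
                   constants = k)
  expect_true(all(diff(ph_alk) > 0))
  ph_dic <- sapply(seq(1800, 2100, 50), function(d) {
    ph_from_alk_dic(2250, d, k)
  })
  expect_true(all(diff(ph_dic) < 0))
})

test_that("unphysical ALK/DIC pairs raise a no-solution error", {
  k <- carb_constants(10, 32)
  expect_error(ph_from_alk_dic(25000, 100, k), "no root")
  expect_error(ph_from_alk_dic(-5, 2000, k), "positive")
})

test_that("alk_from_ph_dic is the closed-form inverse of the solver", {
  k <- carb_constants(10, 30.3)
  for (alk in c(2100, 2250, 2400)) {
    ph <- ph_from_alk_dic(alk, 2000, k)
    expect_equal(alk_from_ph_dic(ph, 2000, k), alk, tolerance = 1e-8)
    expect_equal(ph_from_alk_dic(alk_from_ph_dic(ph, 2000, k), 2000, k), ph,
                 tolerance = 1e-6 / 8)
  }
  # DIC -> 0 limit: only borate and water alkalinity remain
  h <- 10^(-8)
  borate_water <- (k$BT * k$KB / (k$KB + h) + k$Kw / h - h) * 1e6
  expect_equal(alk_from_ph_dic(8, 0, k), borate_water, tolerance = 1e-10)
})

test_that("alkalinity change for the 7.7 -> 7.9 step depends on the closure", {
  # frozen closed-form evaluations at T = 10, S = 30.3, DIC = 2050 /
  # pCO2 = 400
  expect_equal(alk_change_for_ph_step(7.7, 7.9, 10, 30.3, "fixed_dic"),
               59.67, tolerance = 0.01)
  expect_equal(alk_change_for_ph_step(7.7, 7.9, 10, 30.3, "fixed_pco2"),
               600.71, tolerance = 0.01)
})

test_that("DIC from pH and pCO2 follows Henry speciation", {
  k <- carb_constants(10, 33)
  dic <- sapply(seq(7.4, 8.4, 0.2), dic_from_ph_pco2, pco2 = 400,
                constants = k)
  expect_true(all(diff(dic) > 0))  # higher pH stores more DIC at fixed pCO2
  # manual closed form
  h <- 10^-8
  manual <- k$K0 * 400e-6 * (1 + k$K1 / h + k$K1 * k$K2 / h^2) * 1e6
  expect_equal(dic_from_ph_pco2(8, 400, k), manual)
})

test_that("seawater_state derives consistent values from any supported pair", {
  st <- seawater_state(11, 34.5, alk = 2235, dic = 2050)
  st2 <- seawater_state(11, 34.5, ph = st$ph, dic = 2050)
  expect_equal(st2$alk, 2235, tolerance = 1e-6)
  st3 <- seawater_state(11, 34.5, ph = st$ph, pco2 = st$pco2)
  expect_equal(st3$dic, 2050, tolerance = 1e-6)
  st4 <- seawater_state(11, 34.5, ph = st$ph, alk = 2235)
  expect_equal(st4$dic, 2050, tolerance = 1e-6)
  expect_error(seawater_state(11, 34.5, alk = 2235), "exactly two")
})

test_that("solver agrees with the scan oracle across random states", {
  set.seed(7)
  n <- 50  # the full 1000-state sweep runs in the acceptance suite
  for (i in seq_len(n)) {
    t <- runif(1, 2, 25); s <- runif(1, 20, 42)
    alk <- runif(1, 1900, 2450)
    dic <- runif(1, 0.8 * alk, 0.98 * alk)
    k <- carb_constants(t, s)
    expect_equal(ph_from_alk_dic(alk, dic, k), ph_scan_oracle(alk, dic, k),
                 tolerance = 1e-4 / 8)
  }
})

test_that("constants dump round-trips through JSON", {
  k <- carb_constants(10, 32)
  js <- constants_json(k)
  back <- jsonlite::fromJSON(js)
  expect_equal(back$K1, k$K1)
  expect_equal(back$salinity, 32)
})
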