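# Monte-Carlo uncertainty propagation.

env_const <- function(years = 2000L, t = 10, s = 30.3) {
  data.frame(year_ce = years, temperature = t, salinity = s)
}

test_that("all-sigmas-zero reconstruction collapses to the deterministic pH", {
  recs <- band_records("A", 2000L, d11b = 28.7, b_conc = 10)
  p0 <- proxy_params(d11b_sw_sd = 0, t_sd = 0, s_sd = 0)
  c0 <- calibration_model(slope_2sd = 0, intercept_2sd = 0)
  r <- reconstruct_ph(recs, env_const(), p0, c0, n_draws = 50, seed = 3,
                      meas_sigma_scale = 0)
  det <- ph_from_skeletal(28.7, pkb_star(10, 30.3))
  expect_equal(r$ph_median, det, tolerance = 1e-12)
  expect_equal(r$ci68_hi - r$ci68_lo, 0)
  expect_equal(r$ci95_hi - r$ci95_lo, 0)
})

test_that("MC median converges to the deterministic estimate", {
  recs <- band_records("A", 2000L, d11b = 28.7, b_conc = 10)
  det <- ph_from_skeletal(28.7, pkb_star(10, 30.3))
  r <- reconstruct_ph(recs, env_const(), n_draws = 1e4, seed = 2)
  expect_lt(abs(r$ph_median - det), 0.005)
})

test_that("envelopes widen as solution boron concentration falls", {
  recs <- band_records("A", 2000L, d11b = 28.7, b_conc = c(40, 15, 5))
  r <- reconstruct_ph(recs, env_const(), n_draws = 4000, seed = 5)
  width <- r$ci68_hi - r$ci68_lo
  expect_true(all(diff(width) > 0))
})

test_that("results are bit-reproducible for a given seed", {
  recs <- band_records("A", 2000L, d11b = c(28.1, 28.7), b_conc = c(8, 20))
  r1 <- reconstruct_ph(recs, env_const(), n_draws = 500, seed = 11)
  r2 <- reconstruct_ph(recs, env_const(), n_draws = 500, seed = 11)
  expect_identical(r1, r2)
  r3 <- reconstruct_ph(recs, env_const(), n_draws = 500, seed = 12)
  expect_false(identical(r1$ph_median, r3$ph_median))
})

test_that("records failing more than half their draws are excluded", {
  recs <- band_records("A", 2000L, d11b = c(28.7, 23.0), b_conc = 10)
  expect_warning(
    r <- reconstruct_ph(recs, env_const(), n_draws = 400, seed = 4),
    "uninvertible")
  expect_equal(nrow(r), 1L)
  expect_equal(r$year_ce, 2000L)
})

test_that("small-noise MC half-width matches first-order error propagation", {
  # shrink every uncertainty by 10x so the pH map is locally linear, then
  # compare the MC 68% half-width with a finite-difference delta method
  sc <- 0.1
  p <- proxy_params(d11b_sw_sd = 0.1 * sc, t_sd = 1 * sc, s_sd = 1 * sc)
  cl <- calibration_model(slope_2sd = 0.06 * sc, intercept_2sd = 0.72 * sc)
  b_conc <- 15; d11b <- 28.2; t0 <- 10; s0 <- 30.3
  f <- function(d11b_, slope_, int_, dsw_, t_, s_) {
    db <- (d11b_ - int_) / slope_
    ph_from_borate(db, pkb_vec_test(t_, s_),
                   proxy_params(d11b_sw = dsw_))
  }
  pkb_vec_test <- function(t, s) pkb_star(t, s)
  base <- c(d11b, 1.46, 6.91, 39.73, t0, s0)
  sds <- c(sc * measurement_2sigma(b_conc) / 2, cl$slope_2sd / 2,
           cl$intercept_2sd / 2, p$d11b_sw_sd, p$t_sd, p$s_sd)
  grad <- vapply(seq_along(base), function(j) {
    h <- max(1e-6, 1e-4 * abs(base[j]))
    xp <- base; xp[j] <- xp[j] + h
    xm <- base; xm[j] <- xm[j] - h
    (do.call(f, as.list(xp)) - do.call(f, as.list(xm))) / (2 * h)
  }, numeric(1))
  analytic <- sqrt(sum((grad * sds)^2))
  recs <- band_records("A", 2000L, d11b = d11b, b_conc = b_conc)
  r <- reconstruct_ph(recs, env_const(2000L, t0, s0), p, cl,
                      n_draws = 2e4, seed = 8, meas_sigma_scale = sc)
  mc_halfwidth <- (r$ci68_hi - r$ci68_lo) / 2
  expect_lt(abs(mc_halfwidth - analytic) / analytic, 0.15)
})

test_that("coverage simulation calibrates the 68% and 95% envelopes", {
  cv <- mc_coverage(n_records = 150, n_draws = 600, seed = 2)
  expect_gt(cv$coverage68, 0.60)
  expect_lt(cv$coverage68, 0.80)
  expect_gt(cv$coverage95, 0.88)
})

test_that("band_records validates flags, concentrations and years", {
  expect_error(band_records("A", 2000, 28, 10, flag = "weird"), "flag")
  expect_error(band_records("A", 2000, 28, b_conc = -2), "positive")
  expect_error(band_records("A", 2030, 28, 10, collection_year = 2020),
               "collection")
})
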