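# B/Ca vs delta-11-B contamination screening.

make_clean_bands <- function(n = 60, seed = 1) {
  set.seed(seed)
  d11b <- runif(n, 27, 29)
  bca <- (d11b - 17.5) / 0.05 + rnorm(n, 0, 5)
  band_records("S1", 2000L, d11b = d11b, b_conc = runif(n, 4, 40),
               bca = bca)
}

test_that("Theil-Sen recovers an exact line", {
  recs <- band_records("S1", 2000L, d11b = 27 + 0.05 * (0:19),
                       b_conc = 10, bca = 200 + 1 * (0:19))
  tr <- fit_bca_trend(recs)
  expect_equal(tr$slope, 0.05)
  expect_equal(tr$intercept, 27 - 0.05 * 200)
})

test_that("Theil-Sen needs enough records and is outlier-resistant", {
  few <- band_records("S1", 2000L, d11b = c(27, 28), b_conc = 10,
                      bca = c(200, 210))
  expect_error(fit_bca_trend(few), "insufficient")
  recs <- make_clean_bands(40)
  tr0 <- fit_bca_trend(recs)
  spoiled <- recs
  spoiled$d11b[1] <- 18; spoiled$bca[1] <- 400  # one worm-like outlier
  tr1 <- fit_bca_trend(spoiled)
  res <- recs$d11b - (tr0$intercept + tr0$slope * recs$bca)
  expect_lt(abs(tr1$slope - tr0$slope) * diff(range(recs$bca)),
            stats::mad(res))
})

test_that("primary synthetic records carry a positive fitted trend", {
  ds <- generate_dataset(scenario_spec(seed = 5))
  tr <- fit_bca_trend(ds$bands)
  expect_gt(tr$slope, 0)
})

test_that("clean data yield no contamination flags", {
  recs <- make_clean_bands(80, seed = 3)
  out <- screen_records(recs)
  expect_true(all(out$flag == "ok"))
  expect_true(all(is.na(out$contam_fraction)))
})

test_that("a band mixed with 10% worm carbonate is flagged", {
  recs <- make_clean_bands(60, seed = 2)
  worm <- contaminant_endmember()
  # contaminate a band in the upper half of the B/Ca range
  i <- which.max(recs$bca)
  recs$d11b[i] <- 0.9 * recs$d11b[i] + 0.1 * worm$d11b
  recs$bca[i] <- 0.9 * recs$bca[i] + 0.1 * worm$bca
  out <- screen_records(recs)
  expect_equal(out$flag[i], "contaminated")
  expect_equal(sum(out$flag == "contaminated"), 1L)
})

test_that("flagging is idempotent and invariant to record order", {
  ds <- generate_dataset(scenario_spec(contam_fraction = 0.05, seed = 9))
  out1 <- screen_records(ds$bands)
  out2 <- screen_records(out1)
  expect_equal(out1$flag, out2$flag)
  perm <- sample(nrow(ds$bands))
  out3 <- screen_records(ds$bands[perm, ])
  expect_equal(out3$flag, out1$flag[perm])
})

test_that("screening recall on the default contaminated scenario is high", {
  hits <- misses <- 0
  for (s in 1:5) {
    ds <- generate_dataset(scenario_spec(contam_fraction = 0.05, seed = s))
    out <- suppressWarnings(screen_records(ds$bands))
    bad <- ds$band_truth$contaminated
    hits <- hits + sum(out$flag[bad] == "contaminated")
    misses <- misses + sum(out$flag[bad] != "contaminated")
  }
  expect_gte(hits / (hits + misses), 0.9)
})

test_that("contamination fraction obeys its mass-balance anchors", {
  tr <- list(slope = 0.05, intercept = 17.5)
  worm <- contaminant_endmember()
  # the contaminant itself
  r1 <- data.frame(d11b = worm$d11b, bca = worm$bca)
  expect_equal(contamination_fraction(r1, tr, worm), 1)
  # a band exactly on the trend
  r2 <- data.frame(d11b = 28, bca = (28 - 17.5) / 0.05)
  expect_equal(contamination_fraction(r2, tr, worm), 0)
  # noise-free 10% mixture recovers exactly
  f <- 0.1
  prim <- c(d11b = 28, bca = (28 - 17.5) / 0.05)
  r3 <- data.frame(d11b = (1 - f) * prim["d11b"] + f * worm$d11b,
                   bca = (1 - f) * prim["bca"] + f * worm$bca)
  expect_equal(contamination_fraction(r3, tr, worm), 0.1, tolerance = 1e-10)
})

test_that("noisy 10% mixtures recover their fraction to ~0.03", {
  set.seed(21)
  worm <- contaminant_endmember()
  tr <- list(slope = 0.05, intercept = 17.5)
  f <- 0.1
  d11b_p <- runif(200, 27, 29)
  bca_p <- (d11b_p - 17.5) / 0.05
  d11b <- (1 - f) * d11b_p + f * worm$d11b +
    rnorm(200, 0, measurement_2sigma(15) / 2)
  bca <- (1 - f) * bca_p + f * worm$bca + rnorm(200, 0, 5)
  est <- contamination_fraction(data.frame(d11b = d11b, bca = bca), tr, worm)
  expect_lt(abs(mean(est) - 0.1), 0.03)
  expect_lt(sd(est), 0.05)
})

test_that("contamination fraction is undefined for boron-poor contaminants", {
  tr <- list(slope = 0.05, intercept = 17.5)
  lowb <- contaminant_endmember(bca = 100, d11b = 18)
  r <- data.frame(d11b = 26, bca = 230)
  expect_true(is.na(contamination_fraction(r, tr, lowb)))
})

test_that("per-specimen and pooled screening agree on a shared trend", {
  ds <- generate_dataset(scenario_spec(contam_fraction = 0.05, seed = 13))
  pooled <- screen_records(ds$bands, screen_params(pooling = "pooled"))
  per <- screen_records(ds$bands, screen_params(pooling = "per_specimen"))
  expect_equal(pooled$flag, per$flag)
})
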