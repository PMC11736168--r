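# Forward model: complete synthetic coralline-algae datasets from a
# prescribed pH history, so that every pipeline stage (dating, screening,
# reconstruction) can be validated against known truth.

#' Scenario specification for the synthetic-data generator
#'
#' The defaults encode the study conditions the package is designed
#' around: a century-long coastal record with quasi-decadal pH
#' oscillation between 7.7 and 7.9, a +0.2 pH ramp over 1980-2000, a
#' warming from ~8 to ~11 degC over 1980-2020, mean salinity 30.3 psu,
#' solution boron concentrations spanning 4-40 ng/g, and optional
#' contamination of a fraction of bands by boron-rich, isotopically light
#' worm carbonate.
#'
#' @param years Integer vector of calendar years (default 1920:2020).
#' @param ph_base Midpoint of the baseline pH oscillation (7.8).
#' @param ph_amp Half-amplitude of the oscillation (0.1, giving 7.7-7.9).
#' @param ph_period_range Oscillation period range, years; one period is
#'   drawn per scenario (8-12 yr).
#' @param ph_step Size of the pH ramp (+0.2).
#' @param step_years Ramp interval, `c(start, end)` (1980-2000).
#' @param t_start,t_end Temperature before 1980 and at 2020, degC (8, 11);
#'   linear in between from 1980, clamped to \[5, 13\] after noise.
#' @param t_sd Interannual temperature noise, 1-sigma degC.
#' @param s_mean,s_sd Salinity mean (30.3 psu) and interannual 1-sigma.
#' @param b_conc_range Solution boron concentration range, ng/g (4-40,
#'   uniform).
#' @param n_specimens Number of specimens (bands = specimens x years).
#' @param contam_fraction Fraction of bands contaminated (default 0).
#' @param contam_mix Contaminant mass fraction within a contaminated band
#'   (default 0.3: the observed contaminated sub-samples were frequently
#'   too low in delta-11-B to invert at all, which requires roughly a
#'   third worm carbonate by mass).
#' @param contaminant A [contaminant_endmember()].
#' @param bca_slope,bca_sd B/Ca forward model: primary
#'   `bca = (d11b - bca_offset)/bca_slope + N(0, bca_sd)` so that d11b
#'   regressed on B/Ca has slope `bca_slope`; defaults 0.05 permil per
#'   umol/mol, offset placing primary B/Ca near 210 umol/mol, noise 5.
#' @param bca_offset See `bca_slope`.
#' @param growth_um_yr Mean annual extension, um/yr (280).
#' @param growth_jitter Fractional growth-rate jitter per year (0.3).
#' @param mgca_mean,mgca_amp Transect Mg/Ca mean and seasonal amplitude,
#'   mmol/mol (150, 30).
#' @param mgca_noise_frac Transect noise as a fraction of the seasonal
#'   amplitude (0.2).
#' @param points_per_year Transect sampling density (20).
#' @param noise Master switch: `FALSE` zeroes every stochastic term
#'   (measurement noise, env noise, B/Ca scatter, growth jitter) for
#'   exact round-trip tests.
#' @param seed Integer seed; every stochastic choice in the generator
#'   derives from it.
#' @return An object of class `scenario_spec` (a list of the above).
#' @export
scenario_spec <- function(years = 1920:2020,
                          ph_base = 7.8, ph_amp = 0.1,
                          ph_period_range = c(8, 12),
                          ph_step = 0.2, step_years = c(1980, 2000),
                          t_start = 8, t_end = 11, t_sd = 0.5,
                          s_mean = 30.3, s_sd = 0.5,
                          b_conc_range = c(4, 40),
                          n_specimens = 2,
                          contam_fraction = 0, contam_mix = 0.3,
                          contaminant = contaminant_endmember(),
                          bca_slope = 0.05, bca_offset = 17.5, bca_sd = 5,
                          growth_um_yr = 280, growth_jitter = 0.3,
                          mgca_mean = 150, mgca_amp = 30,
                          mgca_noise_frac = 0.2,
                          points_per_year = 20,
                          noise = TRUE, seed = 1L) {
  spec <- list(years = as.integer(years), ph_base = ph_base, ph_amp = ph_amp,
               ph_period_range = ph_period_range, ph_step = ph_step,
               step_years = step_years, t_start = t_start, t_end = t_end,
               t_sd = t_sd, s_mean = s_mean, s_sd = s_sd,
               b_conc_range = b_conc_range, n_specimens = n_specimens,
               contam_fraction = contam_fraction, contam_mix = contam_mix,
               contaminant = contaminant, bca_slope = bca_slope,
               bca_offset = bca_offset, bca_sd = bca_sd,
               growth_um_yr = growth_um_yr, growth_jitter = growth_jitter,
               mgca_mean = mgca_mean, mgca_amp = mgca_amp,
               mgca_noise_frac = mgca_noise_frac,
               points_per_year = points_per_year,
               noise = isTRUE(noise), seed = as.integer(seed))
  stopifnot(length(spec$years) >= 2, ph_amp >= 0,
            ph_period_range[1] > 0, diff(ph_period_range) >= 0,
            contam_fraction >= 0, contam_fraction <= 1,
            contam_mix >= 0, contam_mix <= 1, n_specimens >= 1)
  hist_range <- range(ph_truth_series(spec))
  if (hist_range[1] < 7.5 || hist_range[2] > 8.3) {
    stop("prescribed pH history leaves [7.5, 8.3]: ",
         paste(round(hist_range, 3), collapse = "-"), call. = FALSE)
  }
  structure(spec, class = "scenario_spec")
}

# deterministic part of the truth pH history (oscillation phase/period
# drawn from the seed, once per scenario)
ph_truth_series <- function(spec) {
  yrs <- spec$years
  set.seed(spec$seed + 101L)
  period <- stats::runif(1, spec$ph_period_range[1], spec$ph_period_range[2])
  phase <- stats::runif(1, 0, 2 * pi)
  ramp <- pmin(pmax((yrs - spec$step_years[1]) /
                      diff(spec$step_years), 0), 1)
  spec$ph_base + spec$ph_amp * sin(2 * pi * yrs / period + phase) +
    spec$ph_step * ramp
}

#' Per-year environmental (temperature, salinity) series
#'
#' Temperature holds near `t_start` until the ramp interval begins, rises
#' linearly to `t_end` at the last year, and carries interannual noise;
#' values are kept within \[5, 13\] degC. Salinity is `s_mean` with
#' interannual noise. Bit-reproducible for a given spec seed.
#'
#' @param spec A [scenario_spec()].
#' @return Data frame `year_ce`, `temperature`, `salinity`.
#' @export
emulate_env <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  yrs <- spec$years
  set.seed(spec$seed + 202L)
  frac <- pmin(pmax((yrs - spec$step_years[1]) /
                      (max(yrs) - spec$step_years[1]), 0), 1)
  t_mean <- spec$t_start + frac * (spec$t_end - spec$t_start)
  t_noise <- if (spec$noise) stats::rnorm(length(yrs), 0, spec$t_sd) else 0
  s_noise <- if (spec$noise) stats::rnorm(length(yrs), 0, spec$s_sd) else 0
  data.frame(
    year_ce = yrs,
    temperature = pmin(pmax(t_mean + t_noise, 5), 13),
    salinity = spec$s_mean + s_noise
  )
}

#' Generate a complete synthetic coralline-algae dataset
#'
#' Runs the full forward model: prescribed pH history -> per-year borate
#' delta-11-B at that year's pKB* -> skeletal delta-11-B through the
#' species calibration -> measurement noise at each band's boron
#' concentration (half the published 2-sigma-vs-\[B\] curve). B/Ca is
#' generated on the primary positive trend against delta-11-B; a chosen
#' fraction of bands is then mixed by mass balance toward the worm
#' endmember (both B/Ca and delta-11-B). A seasonal Mg/Ca transect with
#' growth-rate jitter is generated per specimen.
#'
#' @param spec A [scenario_spec()].
#' @param params A [proxy_params()] (the forward model uses its
#'   `alpha_b`, `d11b_sw`).
#' @param cal A [calibration_model()].
#' @return List of class `synthetic_dataset` with elements
#'   `truth` (year_ce, ph_true, pkb), `env` (from [emulate_env()]),
#'   `bands` (a [band_records()] table, `flag` all `"ok"` — screening is
#'   the pipeline's job), `band_truth` (specimen_id, year_ce,
#'   contaminated, contam_mix), `transects` (specimen_id, distance_um,
#'   mgca), and `spec`.
#' @export
generate_dataset <- function(spec = scenario_spec(),
                             params = proxy_params(),
                             cal = calibration_model()) {
  stopifnot(inherits(spec, "scenario_spec"))
  yrs <- spec$years
  ny <- length(yrs)
  ph_true <- ph_truth_series(spec)
  env <- emulate_env(spec)
  pkb <- pkb_vec(env$temperature, env$salinity)
  truth <- data.frame(year_ce = yrs, ph_true = ph_true, pkb = pkb)

  set.seed(spec$seed + 303L)
  specs_id <- sprintf("SYN%02d", seq_len(spec$n_specimens))
  bands <- do.call(rbind, lapply(specs_id, function(sid) {
    data.frame(specimen_id = sid, year_ce = yrs,
               ph_true = ph_true, pkb = pkb)
  }))
  n <- nrow(bands)
  db_true <- borate_from_ph(bands$ph_true, bands$pkb, params)
  d11b_clean <- skeletal_from_borate(db_true, cal)
  b_conc <- stats::runif(n, spec$b_conc_range[1], spec$b_conc_range[2])
  meas_sd <- if (spec$noise) measurement_2sigma(b_conc) / 2 else 0
  d11b <- d11b_clean + stats::rnorm(n, 0, meas_sd)
  bca_sd <- if (spec$noise) spec$bca_sd else 0
  bca <- (d11b_clean - spec$bca_offset) / spec$bca_slope +
    stats::rnorm(n, 0, bca_sd)

  contaminated <- rep(FALSE, n)
  if (spec$contam_fraction > 0) {
    n_bad <- round(spec$contam_fraction * n)
    contaminated[sample.int(n, n_bad)] <- TRUE
    f <- spec$contam_mix
    d11b[contaminated] <- (1 - f) * d11b[contaminated] +
      f * spec$contaminant$d11b
    bca[contaminated] <- (1 - f) * bca[contaminated] +
      f * spec$contaminant$bca
  }

  band_tab <- band_records(
    specimen_id = bands$specimen_id, year_ce = bands$year_ce,
    d11b = d11b, b_conc = b_conc, bca = bca, flag = "ok",
    collection_year = max(yrs)
  )
  band_truth <- data.frame(
    specimen_id = bands$specimen_id, year_ce = bands$year_ce,
    ph_true = bands$ph_true, contaminated = contaminated,
    contam_mix = ifelse(contaminated, spec$contam_mix, 0)
  )

  transects <- do.call(rbind, lapply(specs_id, function(sid) {
    simulate_transect(spec, sid)
  }))

  structure(list(truth = truth, env = env, bands = band_tab,
                 band_truth = band_truth, transects = transects,
                 spec = spec),
            class = "synthetic_dataset")
}

# seasonal Mg/Ca transect for one specimen: annual sinusoid sampled from
# the surface (youngest) downward, with per-year growth-rate jitter
simulate_transect <- function(spec, sid) {
  yrs <- spec$years
  ny <- length(yrs)
  set.seed(spec$seed + 404L + sum(utf8ToInt(sid)))
  jit <- if (spec$noise) {
    stats::runif(ny, 1 - spec$growth_jitter, 1 + spec$growth_jitter)
  } else rep(1, ny)
  widths <- spec$growth_um_yr * jit          # oldest..youngest year widths
  # surface = collection; distance increases with age
  widths_young_first <- rev(widths)
  offsets <- cumsum(c(0, widths_young_first[-ny]))
  pts <- lapply(seq_len(ny), function(i) {
    ppy <- spec$points_per_year
    frac <- (seq_len(ppy) - 0.5) / ppy      # position within the year band
    dist <- offsets[i] + frac * widths_young_first[i]
    # summer maximum mid-band; phase chosen so each band holds one cycle
    mg <- spec$mgca_mean + spec$mgca_amp * cos(2 * pi * (frac - 0.5))
    data.frame(distance_um = dist, mgca = mg)
  })
  tr <- do.call(rbind, pts)
  if (spec$noise) {
    tr$mgca <- tr$mgca + stats::rnorm(nrow(tr), 0,
                                      spec$mgca_noise_frac * spec$mgca_amp)
  }
  data.frame(specimen_id = sid, tr)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic coralline-algae dataset: %d-%d CE, %d specimen(s), %d bands\n",
    min(x$spec$years), max(x$spec$years), x$spec$n_specimens,
    nrow(x$bands)))
  cat(sprintf("  contamination: %.0f%% of bands at %.0f%% worm mix; seed %d\n",
              100 * x$spec$contam_fraction, 100 * x$spec$contam_mix,
              x$spec$seed))
  invisible(x)
}
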