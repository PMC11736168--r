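#' Boron proxy parameter set
#'
#' Bundles the constants of the boron-isotope pH proxy together with the
#' 1-sigma uncertainties used by the Monte-Carlo error propagation.
#'
#' `d11b_sw` defaults to 39.73 permil, the mean of five local surface
#' seawater measurements; the open-ocean compilation value 39.61 permil is
#' the standard alternative. `alpha_b` = 1.0272 is the equilibrium boron
#' isotope fractionation factor between boric acid and borate (Klochko et
#' al. 2006).
#'
#' @param alpha_b Boric acid / borate fractionation factor (> 1).
#' @param d11b_sw Seawater delta-11-B, permil (must lie in \[39, 41\]).
#' @param d11b_sw_sd 1-sigma uncertainty on `d11b_sw`, permil.
#' @param t_sd 1-sigma uncertainty on water temperature, degC.
#' @param s_sd 1-sigma uncertainty on salinity, psu.
#' @return An object of class `proxy_params`.
#' @export
proxy_params <- function(alpha_b = 1.0272, d11b_sw = 39.73,
                         d11b_sw_sd = 0.1, t_sd = 1, s_sd = 1) {
  if (!is.finite(alpha_b) || alpha_b <= 1) {
    stop("`alpha_b` must be > 1", call. = FALSE)
  }
  if (!is.finite(d11b_sw) || d11b_sw < 39 || d11b_sw > 41) {
    stop("`d11b_sw` must lie in [39, 41] permil, got ", d11b_sw,
         call. = FALSE)
  }
  stopifnot(d11b_sw_sd >= 0, t_sd >= 0, s_sd >= 0)
  structure(list(alpha_b = alpha_b, d11b_sw = d11b_sw,
                 d11b_sw_sd = d11b_sw_sd, t_sd = t_sd, s_sd = s_sd),
            class = "proxy_params")
}

#' Species calibration between skeletal and borate delta-11-B
#'
#' Linear calibration tying the skeletal delta-11-B of cultured
#' *Clathromorphum compactum* to the delta-11-B of seawater borate:
#' \deqn{\delta^{11}B_{skeletal} = 1.46\,\delta^{11}B_{borate} + 6.91}
#' with 2-sigma uncertainties of 0.06 on the slope and 0.72 permil on the
#' intercept.
#'
#' @param slope,intercept Calibration coefficients (slope dimensionless,
#'   intercept permil).
#' @param slope_2sd,intercept_2sd Their 2-sigma uncertainties.
#' @return An object of class `calibration_model`.
#' @export
calibration_model <- function(slope = 1.46, intercept = 6.91,
                              slope_2sd = 0.06, intercept_2sd = 0.72) {
  if (!is.finite(slope) || slope <= 0) {
    stop("calibration `slope` must be positive", call. = FALSE)
  }
  stopifnot(slope_2sd >= 0, intercept_2sd >= 0)
  structure(list(slope = slope, intercept = intercept,
                 slope_2sd = slope_2sd, intercept_2sd = intercept_2sd),
            class = "calibration_model")
}

#' Analytical 2-sigma uncertainty of a delta-11-B measurement
#'
#' Long-term reproducibility of carbonate delta-11-B measurements falls with
#' the boron concentration of the analysed solution following a double
#' exponential fitted to repeat reference-material analyses:
#' \deqn{2\sigma = 1.61\,e^{-0.22 [B]} + 0.17\,e^{-0.002 [B]}}
#' with \[B\] in ng/g.
#'
#' @param b_conc Boron concentration of the analysed solution, ng/g
#'   (vectorised, must be >= 0).
#' @return 2-sigma measurement uncertainty, permil.
#' @examples
#' measurement_2sigma(c(5, 10, 20))
#' @export
measurement_2sigma <- function(b_conc) {
  if (!is.numeric(b_conc) || any(!is.finite(b_conc)) || any(b_conc < 0)) {
    stop("`b_conc` must be non-negative finite values (ng/g)", call. = FALSE)
  }
  1.61 * exp(-0.22 * b_conc) + 0.17 * exp(-0.002 * b_conc)
}

#' Borate delta-11-B from skeletal delta-11-B
#'
#' Inverts the species calibration:
#' \eqn{\delta^{11}B_{borate} = (\delta^{11}B_{skeletal} - b)/m}.
#'
#' @param d11b_skel Skeletal delta-11-B, permil (vectorised).
#' @param cal A [calibration_model()].
#' @return Borate delta-11-B, permil.
#' @export
borate_from_skeletal <- function(d11b_skel, cal = calibration_model()) {
  stopifnot(inherits(cal, "calibration_model"))
  (d11b_skel - cal$intercept) / cal$slope
}

#' Skeletal delta-11-B from borate delta-11-B (forward calibration)
#'
#' @param d11b_borate Borate delta-11-B, permil (vectorised).
#' @inheritParams borate_from_skeletal
#' @return Skeletal delta-11-B, permil.
#' @export
skeletal_from_borate <- function(d11b_borate, cal = calibration_model()) {
  stopifnot(inherits(cal, "calibration_model"))
  cal$slope * d11b_borate + cal$intercept
}

#' Seawater pH from borate delta-11-B
#'
#' The delta-11-B of the borate ion rises with seawater pH; inverting the
#' borate-boric acid isotope mass balance gives
#' \deqn{pH = pK_B^* - \log_{10}\!\left(-\frac{\delta_{sw} - \delta_b}
#'   {\delta_{sw} - \alpha_B\,\delta_b - 1000(\alpha_B - 1)}\right)}
#' where \eqn{\delta_b} is the borate delta-11-B. Values of \eqn{\delta_b}
#' so low that the log argument is not positive cannot correspond to any
#' seawater pH; these return `NA` with a warning (or an error when
#' `on_uninvertible = "error"`).
#'
#' @param d11b_borate Borate delta-11-B, permil (vectorised).
#' @param pkb pKB* on the total scale (scalar or same length).
#' @param params A [proxy_params()].
#' @param on_uninvertible `"na"` (default) or `"error"`.
#' @return Total-scale pH, same length as `d11b_borate`.
#' @examples
#' ph_from_borate(borate_from_skeletal(28.7), pkb = 8.82)
#' @export
ph_from_borate <- function(d11b_borate, pkb, params = proxy_params(),
                           on_uninvertible = c("na", "error")) {
  stopifnot(inherits(params, "proxy_params"))
  on_uninvertible <- match.arg(on_uninvertible)
  dsw <- params$d11b_sw
  a <- params$alpha_b
  num <- -(dsw - d11b_borate)
  den <- dsw - a * d11b_borate - 1000 * (a - 1)
  arg <- num / den
  bad <- !is.finite(arg) | arg <= 0
  if (any(bad)) {
    msg <- paste0(sum(bad), " delta-11-B value(s) too low to correspond ",
                  "to any seawater pH (non-positive log argument)")
    if (on_uninvertible == "error") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
    arg[bad] <- NA_real_
  }
  pkb - log10(arg)
}

#' Borate delta-11-B from seawater pH (forward proxy model)
#'
#' Exact algebraic inverse of [ph_from_borate()], used by the synthetic-data
#' forward model.
#'
#' @param ph Total-scale pH in \[2, 12\] (vectorised).
#' @inheritParams ph_from_borate
#' @return Borate delta-11-B, permil.
#' @export
borate_from_ph <- function(ph, pkb, params = proxy_params()) {
  stopifnot(inherits(params, "proxy_params"))
  if (any(!is.finite(ph) | ph < 2 | ph > 12)) {
    stop("`ph` must lie in [2, 12]", call. = FALSE)
  }
  dsw <- params$d11b_sw
  a <- params$alpha_b
  r <- 10^(pkb - ph)  # = [B(OH)3]/[B(OH)4-]
  # isotope mass balance: dsw = (r a db + 1000 r (a-1) + db) / (r a + 1)... solve
  # forward from ph_from_borate: arg = r  =>  -(dsw - db) = r (dsw - a db - 1000(a-1))
  (dsw + r * (dsw - 1000 * (a - 1))) / (1 + r * a)
}

#' Seawater pH from a skeletal delta-11-B measurement (deterministic)
#'
#' Chains the calibration inversion and the borate equation; the worked
#' modern-sample example (28.7 permil in the 2018 band, pKB* = 8.82) gives
#' pH 7.87.
#'
#' @param d11b_skel Skeletal delta-11-B, permil (vectorised).
#' @param pkb pKB* on the total scale.
#' @param params A [proxy_params()].
#' @param cal A [calibration_model()].
#' @inheritParams ph_from_borate
#' @return Total-scale pH.
#' @examples
#' ph_from_skeletal(28.7, pkb = 8.82)  # 7.87
#' @export
ph_from_skeletal <- function(d11b_skel, pkb, params = proxy_params(),
                             cal = calibration_model(),
                             on_uninvertible = c("na", "error")) {
  ph_from_borate(borate_from_skeletal(d11b_skel, cal), pkb, params,
                 on_uninvertible = on_uninvertible)
}

#' Local surface-seawater delta-11-B measurements
#'
#' Five surface seawater boron-isotope measurements from the Schoodic
#' Point site (44.373 N, 68.077 W) collected 2016-2017. Their mean,
#' 39.73 permil (2-sigma 0.08), is the package's default seawater
#' delta-11-B; it sits within uncertainty of the open-ocean compilation
#' value of 39.61 +/- 0.2 permil.
#'
#' @return Data frame with `site`, `collection_date`, `temperature_c`,
#'   `d11b_sw_permil`.
#' @examples
#' mean(schoodic_seawater_d11b()$d11b_sw_permil)
#' @export
schoodic_seawater_d11b <- function() {
  utils::read.csv(system.file("extdata", "schoodic_seawater_d11b.csv",
                              package = "paleopH"),
                  stringsAsFactors = FALSE)
}
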