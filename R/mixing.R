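# Conservative endmember mixing with carbonate-system pH evaluation.
#
# Alkalinity, DIC and salinity mix linearly by mass fraction; pH does not,
# and is re-solved for each mixture at a fixed scenario temperature.

#' Define a water-mass endmember
#'
#' @param name Label.
#' @param alk Total alkalinity, umol/kg.
#' @param dic Dissolved inorganic carbon, umol/kg.
#' @param salinity psu (0 allowed for pure river water).
#' @return An object of class `endmember`.
#' @export
endmember <- function(name, alk, dic, salinity) {
  stopifnot(is.finite(alk), alk > 0, is.finite(dic), dic > 0,
            is.finite(salinity), salinity >= 0)
  structure(list(name = as.character(name), alk = alk, dic = dic,
                 salinity = salinity), class = "endmember")
}

#' Gulf of Maine water-mass endmembers
#'
#' The three slope/shelf water masses feeding the Gulf of Maine with their
#' assumed carbonate-system compositions: Warm Slope Water (WSW, Gulf
#' Stream derived; ALK 2375, DIC 2050, S 36.5), Labrador Slope Water (LSW;
#' 2200, 2050, 34) and Scotian Shelf Water (SSW; 2150, 2000, 32), all in
#' umol/kg and psu.
#'
#' @return Named list of three [endmember()] objects: `WSW`, `LSW`, `SSW`.
#' @export
gom_endmembers <- function() {
  list(WSW = endmember("WSW", 2375, 2050, 36.5),
       LSW = endmember("LSW", 2200, 2050, 34),
       SSW = endmember("SSW", 2150, 2000, 32))
}

#' Mix endmembers conservatively and solve the mixture pH
#'
#' @param endmembers List of [endmember()] objects.
#' @param fractions Numeric mixing fractions, same length, each in \[0, 1\]
#'   and summing to 1 within 1e-9.
#' @param temperature Scenario temperature, degC (fixed, not mixed).
#' @return A [seawater_state()] for the mixture. A warning is issued by the
#'   constants routine when the mixture salinity falls below 19 psu.
#' @examples
#' em <- gom_endmembers()
#' mix_waters(list(em$WSW, em$LSW), c(0.7, 0.3), temperature = 11)
#' @export
mix_waters <- function(endmembers, fractions, temperature) {
  if (!all(vapply(endmembers, inherits, logical(1), "endmember"))) {
    stop("`endmembers` must be a list of endmember objects", call. = FALSE)
  }
  if (length(fractions) != length(endmembers)) {
    stop("`fractions` must match `endmembers` in length", call. = FALSE)
  }
  if (any(fractions < 0 | fractions > 1) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop("invalid scenario: fractions must lie in [0, 1] and sum to 1 ",
         "(got sum ", format(sum(fractions), digits = 12), ")",
         call. = FALSE)
  }
  alk <- sum(fractions * vapply(endmembers, `[[`, numeric(1), "alk"))
  dic <- sum(fractions * vapply(endmembers, `[[`, numeric(1), "dic"))
  sal <- sum(fractions * vapply(endmembers, `[[`, numeric(1), "salinity"))
  seawater_state(temperature, sal, alk = alk, dic = dic)
}

#' Warm Slope Water fraction sweep
#'
#' pH of WSW/LSW mixtures as the Warm Slope Water fraction varies, the
#' remainder being Labrador Slope Water (the observed post-1960s water-mass
#' trade), evaluated at one or more fixed temperatures.
#'
#' @param f_wsw Numeric grid of WSW fractions in \[0, 1\].
#' @param temperatures degC values to evaluate (default `c(8, 11)`, the
#'   1980s-to-2000s warming span).
#' @param endmembers A list with `WSW` and `LSW` entries; defaults to
#'   [gom_endmembers()].
#' @return Data frame with `f_wsw`, `temperature`, `alk`, `dic`,
#'   `salinity`, `ph`; pH is monotone increasing in `f_wsw` at fixed
#'   temperature.
#' @export
wsw_sweep <- function(f_wsw = seq(0, 1, 0.05), temperatures = c(8, 11),
                      endmembers = gom_endmembers()) {
  stopifnot(all(f_wsw >= 0 & f_wsw <= 1))
  grid <- expand.grid(f_wsw = f_wsw, temperature = temperatures,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    st <- mix_waters(list(endmembers$WSW, endmembers$LSW),
                     c(grid$f_wsw[i], 1 - grid$f_wsw[i]),
                     grid$temperature[i])
    data.frame(f_wsw = grid$f_wsw[i], temperature = grid$temperature[i],
               alk = st$alk, dic = st$dic, salinity = st$salinity,
               ph = st$ph)
  })
  do.call(rbind, res)
}

#' Three-way water-mass mixing grid
#'
#' All compositions of the WSW/LSW/SSW simplex at a given resolution, with
#' the mixture pH solved at a fixed temperature (and optionally a fixed
#' salinity, as in contour-plot presentations that isolate the ALK:DIC
#' effect).
#'
#' @param resolution Number of grid levels per axis (>= 2); the grid holds
#'   `choose(resolution + 1, 2)` simplex points.
#' @param temperature degC.
#' @param fixed_salinity Optional psu value overriding the mixed salinity.
#' @param endmembers As in [wsw_sweep()], needing `WSW`, `LSW`, `SSW`.
#' @return Data frame `f_wsw`, `f_lsw`, `f_ssw`, `salinity`, `ph`.
#' @export
ternary_grid <- function(resolution = 11, temperature = 11,
                         fixed_salinity = NULL,
                         endmembers = gom_endmembers()) {
  stopifnot(resolution >= 2)
  steps <- seq(0, 1, length.out = resolution)
  grid <- expand.grid(f_wsw = steps, f_lsw = steps, KEEP.OUT.ATTRS = FALSE)
  grid$f_ssw <- 1 - grid$f_wsw - grid$f_lsw
  grid <- grid[grid$f_ssw > -1e-9, , drop = FALSE]
  grid$f_ssw <- pmax(grid$f_ssw, 0)
  em <- list(endmembers$WSW, endmembers$LSW, endmembers$SSW)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    fr <- c(grid$f_wsw[i], grid$f_lsw[i], grid$f_ssw[i])
    alk <- sum(fr * vapply(em, `[[`, numeric(1), "alk"))
    dic <- sum(fr * vapply(em, `[[`, numeric(1), "dic"))
    sal <- sum(fr * vapply(em, `[[`, numeric(1), "salinity"))
    sal_used <- if (is.null(fixed_salinity)) sal else fixed_salinity
    ph <- ph_from_alk_dic(alk, dic, carb_constants(temperature, sal_used))
    data.frame(f_wsw = fr[1], f_lsw = fr[2], f_ssw = fr[3],
               salinity = sal_used, ph = ph)
  })
  do.call(rbind, out)
}

# river DIC (umol/kg) for a given river pH: either linear interpolation of
# the published pairs (pH 6.6 -> 428, pH 7.2 -> 261) or solved from
# (ALK, pH) at the river salinity with the package's own constants
river_dic_for_ph <- function(river_ph, river_alk, mode, river_salinity) {
  if (mode == "caption") {
    428 + (river_ph - 6.6) * (261 - 428) / (7.2 - 6.6)
  } else {
    k <- carb_constants(10, river_salinity)
    dic_from_ph_alk(river_ph, river_alk, k)
  }
}

#' River-seawater mixing model
#'
#' Mixes low-alkalinity river water (ALK 230 umol/kg; DIC set by the river
#' pH) conservatively with Gulf of Maine seawater (ALK 2200, DIC 2050,
#' S 33; unmixed pH 8.0 at the default 10 degC) and solves the coastal
#' mixture pH. River DIC comes either from the published pH-DIC pairs
#' (428 umol/kg at river pH 6.6, 261 at 7.2; `river_dic = "caption"`,
#' linearly interpolated in pH) or is recomputed from (ALK, pH)
#' (`river_dic = "solve"`).
#'
#' @param f_river River mass fraction in \[0, 1\] (vectorised).
#' @param river_ph River water pH in \[6, 8\] (scalar).
#' @param temperature Mixture temperature, degC (default 10, at which the
#'   unmixed seawater endmember sits at pH 8.0).
#' @param river_alk River alkalinity, umol/kg.
#' @param river_dic `"caption"` or `"solve"` (see above).
#' @param river_salinity River salinity, psu (used by `"solve"` and for
#'   the mixture salinity; 0 = fresh).
#' @param seawater An [endmember()] for the marine side.
#' @return Data frame `f_river`, `river_ph`, `alk`, `dic`, `salinity`,
#'   `ph`, one row per `f_river`. Mixtures below 19 psu trigger the
#'   low-salinity warning from the constants routine; mixtures whose
#'   salinity reaches 0 are unphysical for the marine constant set and
#'   return `NA` pH.
#' @export
river_mix <- function(f_river, river_ph, temperature = 10,
                      river_alk = 230,
                      river_dic = c("caption", "solve"),
                      river_salinity = 0,
                      seawater = endmember("GoM", 2200, 2050, 33)) {
  river_dic <- match.arg(river_dic)
  stopifnot(all(f_river >= 0 & f_river <= 1))
  if (!is.finite(river_ph) || river_ph < 6 || river_ph > 8) {
    stop("`river_ph` must lie in [6, 8]", call. = FALSE)
  }
  rdic <- river_dic_for_ph(river_ph, river_alk, river_dic, river_salinity)
  alk <- f_river * river_alk + (1 - f_river) * seawater$alk
  dic <- f_river * rdic + (1 - f_river) * seawater$dic
  sal <- f_river * river_salinity + (1 - f_river) * seawater$salinity
  ph <- vapply(seq_along(f_river), function(i) {
    if (sal[i] <= 0) return(NA_real_)
    ph_from_alk_dic(alk[i], dic[i], carb_constants(temperature, sal[i]))
  }, numeric(1))
  data.frame(f_river = f_river, river_ph = river_ph, alk = alk, dic = dic,
             salinity = sal, ph = ph)
}

#' Coastal pH shift between two river-pH eras
#'
#' For each river fraction, the difference in mixed coastal pH between a
#' later (higher river pH) and an earlier (lower river pH) scenario — the
#' effect a rise in river pH alone could have had on coastal waters.
#'
#' @param f_river Vector of river fractions.
#' @param river_ph_early,river_ph_late The two river pH values (default
#'   6.6 and 7.2, the observed 1980 and 2000 values).
#' @param ... Passed to [river_mix()].
#' @return Data frame `f_river`, `ph_early`, `ph_late`, `delta_ph`.
#' @export
river_ph_shift <- function(f_river = seq(0, 0.99, 0.01),
                           river_ph_early = 6.6, river_ph_late = 7.2,
                           ...) {
  early <- river_mix(f_river, river_ph_early, ...)
  late <- river_mix(f_river, river_ph_late, ...)
  data.frame(f_river = f_river, ph_early = early$ph, ph_late = late$ph,
             delta_ph = late$ph - early$ph)
}

#' Sensitivity of the river-mixing conclusion to assumed river alkalinity
#'
#' Repeats the river-pH-shift sweep with river alkalinity scaled by the
#' given factors and reports, for each, the smallest river fraction at
#' which the between-era pH shift reaches a threshold.
#'
#' @param alk_scale Multipliers on the 230 umol/kg river alkalinity.
#' @param threshold pH shift to reach (default 0.2, the reconstructed
#'   step).
#' @param f_river Sweep grid.
#' @param ... Passed to [river_ph_shift()] / [river_mix()].
#' @return Data frame `alk_scale`, `river_alk`, `f_river_threshold` (NA if
#'   never reached on the grid).
#' @export
river_sensitivity <- function(alk_scale = c(0.5, 1, 1.5), threshold = 0.2,
                              f_river = seq(0, 0.99, 0.01), ...) {
  out <- lapply(alk_scale, function(sc) {
    sweep <- river_ph_shift(f_river, river_alk = 230 * sc, ...)
    hit <- which(!is.na(sweep$delta_ph) & sweep$delta_ph >= threshold)
    data.frame(alk_scale = sc, river_alk = 230 * sc,
               f_river_threshold = if (length(hit)) f_river[min(hit)]
               else NA_real_)
  })
  do.call(rbind, out)
}
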