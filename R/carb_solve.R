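# Carbonate-system speciation and solvers.
#
# Internal convention: all concentrations in mol/kg inside this file; the
# exported interface uses umol/kg (alkalinity, DIC) and uatm (pCO2), the
# units oceanographers print.

# Total alkalinity (mol/kg) at hydrogen-ion activity H (mol/kg, total scale)
# given DIC (mol/kg): ALK = HCO3 + 2 CO3 + B(OH)4 + OH - H.
# No nutrient (Si, P) terms: the mixing and proxy models here carry
# ALK/DIC/T/S only.
alk_balance <- function(H, dic, k) {
  denom <- H^2 + k$K1 * H + k$K1 * k$K2
  dic * (k$K1 * H + 2 * k$K1 * k$K2) / denom +
    k$BT * k$KB / (k$KB + H) +
    k$Kw / H - H
}

#' Solve seawater pH from total alkalinity and DIC
#'
#' Finds the unique total-scale pH satisfying the alkalinity balance
#' \deqn{ALK = [HCO_3^-] + 2[CO_3^{2-}] + [B(OH)_4^-] + [OH^-] - [H^+]}
#' with carbonate speciation set by DIC, by Brent-style bracketing on
#' pH in \[2, 12\] (deterministic, tolerance 1e-8 pH or better).
#'
#' @param alk Total alkalinity, umol/kg.
#' @param dic Dissolved inorganic carbon, umol/kg.
#' @param constants A [carb_constants()] object fixing temperature, salinity
#'   and the equilibrium constants.
#' @return Total-scale pH (scalar). The returned root satisfies the
#'   alkalinity balance to well under 0.01 umol/kg.
#' @examples
#' ph_from_alk_dic(2235, 2050, carb_constants(11, 34.5))
#' @export
ph_from_alk_dic <- function(alk, dic, constants) {
  stopifnot(inherits(constants, "carb_constants"))
  if (!is.finite(alk) || !is.finite(dic) || alk <= 0 || dic <= 0) {
    stop("`alk` and `dic` must be positive finite values (umol/kg)",
         call. = FALSE)
  }
  f <- function(ph) alk_balance(10^(-ph), dic * 1e-6, constants) - alk * 1e-6
  flo <- f(2); fhi <- f(12)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) {
    stop("alkalinity balance has no root in pH [2, 12]: the ALK/DIC pair ",
         "(", alk, ", ", dic, ") is unphysical at T = ",
         constants$temperature, " degC, S = ", constants$salinity,
         call. = FALSE)
  }
  stats::uniroot(f, c(2, 12), f.lower = flo, f.upper = fhi,
                 tol = 1e-10)$root
}

#' Total alkalinity from pH and DIC (closed form)
#'
#' Direct (non-iterative) evaluation of the alkalinity balance at a given
#' total-scale pH and DIC; the exact inverse of [ph_from_alk_dic()].
#'
#' @param ph Total-scale pH in \[2, 12\].
#' @param dic Dissolved inorganic carbon, umol/kg.
#' @inheritParams ph_from_alk_dic
#' @return Total alkalinity, umol/kg.
#' @export
alk_from_ph_dic <- function(ph, dic, constants) {
  stopifnot(inherits(constants, "carb_constants"))
  if (!is.finite(ph) || ph < 2 || ph > 12) {
    stop("`ph` must lie in [2, 12], got ", ph, call. = FALSE)
  }
  if (!is.finite(dic) || dic < 0) {
    stop("`dic` must be a non-negative finite value (umol/kg)", call. = FALSE)
  }
  alk_balance(10^(-ph), dic * 1e-6, constants) * 1e6
}

#' DIC from pH and pCO2
#'
#' With the aqueous CO2 concentration fixed by Henry's law,
#' \eqn{[CO_2^*] = K_0\, pCO_2}, DIC follows in closed form:
#' \eqn{DIC = [CO_2^*](1 + K_1/[H] + K_1 K_2/[H]^2)}.
#'
#' @param ph Total-scale pH.
#' @param pco2 CO2 partial pressure, uatm.
#' @inheritParams ph_from_alk_dic
#' @return Dissolved inorganic carbon, umol/kg.
#' @export
dic_from_ph_pco2 <- function(ph, pco2, constants) {
  stopifnot(inherits(constants, "carb_constants"))
  if (!is.finite(ph) || ph < 2 || ph > 12) {
    stop("`ph` must lie in [2, 12], got ", ph, call. = FALSE)
  }
  if (!is.finite(pco2) || pco2 <= 0) {
    stop("`pco2` must be a positive finite value (uatm)", call. = FALSE)
  }
  H <- 10^(-ph)
  co2star <- constants$K0 * pco2 * 1e-6
  co2star * (1 + constants$K1 / H + constants$K1 * constants$K2 / H^2) * 1e6
}

# pCO2 (uatm) from pH and DIC (umol/kg)
pco2_from_ph_dic <- function(ph, dic, constants) {
  H <- 10^(-ph)
  denom <- H^2 + constants$K1 * H + constants$K1 * constants$K2
  co2star <- dic * 1e-6 * H^2 / denom
  co2star / constants$K0 * 1e6
}

# DIC (umol/kg) from pH and ALK (umol/kg): carbonate alkalinity obtained by
# stripping borate, OH and H from total alkalinity, then inverted in closed
# form.
dic_from_ph_alk <- function(ph, alk, constants) {
  H <- 10^(-ph)
  alk_c <- alk * 1e-6 -
    constants$BT * constants$KB / (constants$KB + H) -
    constants$Kw / H + H
  denom <- constants$K1 * H + 2 * constants$K1 * constants$K2
  alk_c * (H^2 + constants$K1 * H + constants$K1 * constants$K2) / denom * 1e6
}

#' Fully speciated seawater state from any supported parameter pair
#'
#' Describes one water parcel by temperature, salinity and its carbonate
#' system. Exactly two of `alk`, `dic`, `ph`, `pco2` must be supplied
#' (supported pairs: alk+dic, ph+dic, ph+pco2, ph+alk); the remaining
#' quantities are derived.
#'
#' @param temperature degC.
#' @param salinity psu.
#' @param alk Total alkalinity, umol/kg.
#' @param dic Dissolved inorganic carbon, umol/kg.
#' @param ph Total-scale pH.
#' @param pco2 uatm.
#' @return An object of class `seawater_state`: list with `temperature`,
#'   `salinity`, `alk`, `dic`, `ph`, `pco2` and the `constants` used.
#' @examples
#' seawater_state(11, 34.5, alk = 2235, dic = 2050)
#' @export
seawater_state <- function(temperature, salinity,
                           alk = NULL, dic = NULL, ph = NULL, pco2 = NULL) {
  given <- !vapply(list(alk, dic, ph, pco2), is.null, logical(1))
  if (sum(given) != 2L) {
    stop("supply exactly two of `alk`, `dic`, `ph`, `pco2`", call. = FALSE)
  }
  k <- carb_constants(temperature, salinity)
  if (!is.null(alk) && !is.null(dic)) {
    ph <- ph_from_alk_dic(alk, dic, k)
  } else if (!is.null(ph) && !is.null(dic)) {
    alk <- alk_from_ph_dic(ph, dic, k)
  } else if (!is.null(ph) && !is.null(pco2)) {
    dic <- dic_from_ph_pco2(ph, pco2, k)
    alk <- alk_from_ph_dic(ph, dic, k)
  } else if (!is.null(ph) && !is.null(alk)) {
    dic <- dic_from_ph_alk(ph, alk, k)
  } else {
    stop("unsupported parameter pair; supported: alk+dic, ph+dic, ",
         "ph+pco2, ph+alk", call. = FALSE)
  }
  if (is.null(pco2)) pco2 <- pco2_from_ph_dic(ph, dic, k)
  structure(
    list(temperature = temperature, salinity = salinity,
         alk = alk, dic = dic, ph = ph, pco2 = pco2, constants = k),
    class = "seawater_state"
  )
}

#' @export
print.seawater_state <- function(x, ...) {
  cat("Seawater state (total pH scale)\n")
  cat(sprintf("  T = %.2f degC  S = %.2f psu\n", x$temperature, x$salinity))
  cat(sprintf("  ALK = %.1f umol/kg  DIC = %.1f umol/kg\n", x$alk, x$dic))
  cat(sprintf("  pH = %.3f  pCO2 = %.1f uatm\n", x$ph, x$pco2))
  invisible(x)
}

#' Alkalinity change required for a pH step
#'
#' How much total alkalinity must rise to move a surface water parcel from
#' `ph_from` to `ph_to`, under one of two closures: `"fixed_pco2"` keeps the
#' parcel equilibrated with a fixed atmospheric pCO2 (DIC re-derived at each
#' pH), `"fixed_dic"` holds DIC constant. The two closures give genuinely
#' different answers; both are reported by the scenario tooling and neither
#' is privileged.
#'
#' @param ph_from,ph_to Total-scale pH endpoints.
#' @param temperature degC.
#' @param salinity psu.
#' @param mode `"fixed_pco2"` or `"fixed_dic"`.
#' @param pco2 Atmospheric pCO2 (uatm) for the fixed-pCO2 closure.
#' @param dic DIC (umol/kg) for the fixed-DIC closure.
#' @return Alkalinity change, umol/kg.
#' @export
alk_change_for_ph_step <- function(ph_from, ph_to, temperature, salinity,
                                   mode = c("fixed_pco2", "fixed_dic"),
                                   pco2 = 400, dic = 2050) {
  mode <- match.arg(mode)
  k <- carb_constants(temperature, salinity)
  if (mode == "fixed_pco2") {
    a1 <- alk_from_ph_dic(ph_from, dic_from_ph_pco2(ph_from, pco2, k), k)
    a2 <- alk_from_ph_dic(ph_to, dic_from_ph_pco2(ph_to, pco2, k), k)
  } else {
    a1 <- alk_from_ph_dic(ph_from, dic, k)
    a2 <- alk_from_ph_dic(ph_to, dic, k)
  }
  a2 - a1
}
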