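#' Seawater carbonate-system equilibrium constants
#'
#' Computes the stoichiometric equilibrium constants needed to speciate the
#' seawater carbonate and borate systems at surface pressure, all on the
#' total hydrogen-ion pH scale and in mol/kg-solution units:
#'
#' * `K0` — CO2 solubility (Weiss 1974), mol kg^-1 atm^-1
#' * `K1`, `K2` — first and second dissociation constants of carbonic acid
#'   (Lueker, Dickson & Keeling 2000)
#' * `KB` — boric acid dissociation (Dickson 1990)
#' * `Kw` — water self-ionisation (DOE 1994 / Millero 1995)
#' * `BT` — total boron, proportional to salinity (Uppstrom 1974), mol/kg
#'
#' The Lueker constants were characterised for salinities of roughly 19-43
#' psu; below 19 psu a warning is issued and the extrapolated values are
#' returned unchanged (they are never clamped).
#'
#' @param temperature Water temperature, degrees Celsius (0-40).
#' @param salinity Practical salinity, psu (0-43, exclusive of 0).
#' @param bt_scale Multiplier on the Uppstrom total-boron/salinity
#'   proportionality; `1` is the standard open-ocean relation.
#' @return An object of class `carb_constants`: a list with elements `K0`,
#'   `K1`, `K2`, `KB`, `Kw` (all mol/kg or mol kg^-1 atm^-1), `BT` (mol/kg),
#'   `temperature` and `salinity`.
#' @references
#' Lueker, T. J., Dickson, A. G. & Keeling, C. D. (2000) Mar. Chem. 70, 105-119.
#' Dickson, A. G. (1990) Deep-Sea Res. A 37, 755-766.
#' Weiss, R. F. (1974) Mar. Chem. 2, 203-215.
#' Uppstrom, L. R. (1974) Deep-Sea Res. 21, 161-162.
#' @examples
#' cs <- carb_constants(11, 32)
#' -log10(cs$K1)  # ~ 6.00
#' @export
carb_constants <- function(temperature, salinity, bt_scale = 1) {
  if (!is.numeric(temperature) || !is.numeric(salinity) ||
      length(temperature) != 1L || length(salinity) != 1L ||
      !is.finite(temperature) || !is.finite(salinity)) {
    stop("`temperature` and `salinity` must be single finite numbers",
         call. = FALSE)
  }
  if (temperature < 0 || temperature > 40) {
    stop("`temperature` must be within [0, 40] degC, got ", temperature,
         call. = FALSE)
  }
  if (salinity <= 0 || salinity > 43) {
    stop("`salinity` must be within (0, 43] psu, got ", salinity,
         call. = FALSE)
  }
  if (salinity < 19) {
    warning("salinity ", salinity, " psu is below 19 psu, the stated ",
            "validity limit of the Lueker carbonic-acid constants; ",
            "values are extrapolated", call. = FALSE)
  }

  TK <- temperature + 273.15
  S  <- salinity
  lnTK <- log(TK)

  # Lueker et al. (2000), total scale, mol/kg-SW
  pK1 <- 3633.86 / TK - 61.2172 + 9.6777 * lnTK -
    0.011555 * S + 0.0001152 * S^2
  pK2 <- 471.78 / TK + 25.929 - 3.16967 * lnTK -
    0.01781 * S + 0.0001122 * S^2

  # Dickson (1990), total scale
  lnKB <- (-8966.90 - 2890.53 * sqrt(S) - 77.942 * S +
             1.728 * S^1.5 - 0.0996 * S^2) / TK +
    148.0248 + 137.1942 * sqrt(S) + 1.62142 * S -
    (24.4344 + 25.085 * sqrt(S) + 0.2474 * S) * lnTK +
    0.053105 * sqrt(S) * TK

  # DOE (1994) / Millero (1995), total scale
  lnKw <- 148.9652 - 13847.26 / TK - 23.6521 * lnTK +
    (118.67 / TK - 5.977 + 1.0495 * lnTK) * sqrt(S) - 0.01615 * S

  # Weiss (1974), mol kg^-1 atm^-1
  lnK0 <- -60.2409 + 93.4517 * (100 / TK) + 23.3585 * log(TK / 100) +
    S * (0.023517 - 0.023656 * (TK / 100) + 0.0047036 * (TK / 100)^2)

  # Uppstrom (1974): 0.0004157 mol/kg at S = 35
  BT <- bt_scale * 0.0004157 * S / 35

  structure(
    list(K0 = exp(lnK0), K1 = 10^(-pK1), K2 = 10^(-pK2),
         KB = exp(lnKB), Kw = exp(lnKw), BT = BT,
         temperature = temperature, salinity = salinity),
    class = "carb_constants"
  )
}

#' @export
print.carb_constants <- function(x, ...) {
  cat("Seawater carbonate-system constants (total pH scale)\n")
  cat(sprintf("  T = %.2f degC, S = %.2f psu\n", x$temperature, x$salinity))
  cat(sprintf("  pK0 = %.4f  pK1 = %.4f  pK2 = %.4f\n",
              -log10(x$K0), -log10(x$K1), -log10(x$K2)))
  cat(sprintf("  pKB = %.4f  pKw = %.4f  BT = %.1f umol/kg\n",
              -log10(x$KB), -log10(x$Kw), x$BT * 1e6))
  invisible(x)
}

#' Stoichiometric boric-acid pK on the total scale
#'
#' Convenience wrapper returning \eqn{pK_B^* = -\log_{10} K_B} at the given
#' temperature and salinity. Averaged over 6-11 degC at 30.3 psu (the local
#' mean surface salinity) it is 8.82, the value used in the worked proxy
#' example.
#'
#' @inheritParams carb_constants
#' @return Numeric scalar, pKB* on the total scale.
#' @examples
#' mean(sapply(6:11, pkb_star, salinity = 30.3))  # ~ 8.82
#' @export
pkb_star <- function(temperature, salinity) {
  -log10(carb_constants(temperature, salinity)$KB)
}

#' Dump a constants set as JSON for audit
#'
#' @param constants A `carb_constants` object.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
constants_json <- function(constants, path = NULL) {
  stopifnot(inherits(constants, "carb_constants"))
  js <- jsonlite::toJSON(unclass(constants), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
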