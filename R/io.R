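# CSV schemas shared by all pipeline stages. All files are comma-separated,
# UTF-8, header row, "." decimal.
#
#   bands:          specimen_id, year_ce, d11b_permil, B_ngg, BCa_umolmol
#                   (+ flag, contam_fraction after screening)
#   transects:      specimen_id, distance_um, MgCa_mmolmol
#   age model:      specimen_id, distance_um, year_ce
#   environment:    year_ce, temperature_c, salinity_psu
#   reconstruction: year_ce, pH_median, ci68_lo, ci68_hi, ci95_lo, ci95_hi,
#                   n_valid_draws

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

#' Read a band-record CSV
#'
#' @param path CSV with columns `specimen_id`, `year_ce`, `d11b_permil`,
#'   `B_ngg`, `BCa_umolmol` (an optional `flag` column is honoured).
#' @param collection_year Optional upper bound on band years.
#' @return A [band_records()] table.
#' @export
read_band_csv <- function(path, collection_year = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("specimen_id", "year_ce", "d11b_permil", "B_ngg",
                        "BCa_umolmol"), path)
  band_records(df$specimen_id, df$year_ce, df$d11b_permil, df$B_ngg,
               df$BCa_umolmol,
               flag = if ("flag" %in% names(df)) df$flag else "ok",
               collection_year = collection_year)
}

#' Write band records to CSV
#'
#' @param records A [band_records()] table.
#' @param path Output path.
#' @param with_flags Include the `flag` (and, when present,
#'   `contam_fraction`) columns.
#' @export
write_band_csv <- function(records, path, with_flags = TRUE) {
  out <- data.frame(specimen_id = records$specimen_id,
                    year_ce = records$year_ce,
                    d11b_permil = records$d11b,
                    B_ngg = records$b_conc,
                    BCa_umolmol = records$bca)
  if (with_flags) {
    out$flag <- records$flag
    if ("contam_fraction" %in% names(records)) {
      out$contam_fraction <- records$contam_fraction
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a Mg/Ca transect CSV
#'
#' @param path CSV with `specimen_id`, `distance_um`, `MgCa_mmolmol`.
#' @return Data frame with `specimen_id`, `distance_um`, `mgca`.
#' @export
read_transect_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("specimen_id", "distance_um", "MgCa_mmolmol"), path)
  data.frame(specimen_id = df$specimen_id, distance_um = df$distance_um,
             mgca = df$MgCa_mmolmol)
}

#' Write a transect CSV
#' @param transect Data frame with `specimen_id`, `distance_um`, `mgca`.
#' @param path Output path.
#' @export
write_transect_csv <- function(transect, path) {
  utils::write.csv(
    data.frame(specimen_id = transect$specimen_id,
               distance_um = transect$distance_um,
               MgCa_mmolmol = transect$mgca),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an environment (per-year T, S) CSV
#' @param path CSV with `year_ce`, `temperature_c`, `salinity_psu`.
#' @return Data frame `year_ce`, `temperature`, `salinity`.
#' @export
read_env_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("year_ce", "temperature_c", "salinity_psu"), path)
  data.frame(year_ce = df$year_ce, temperature = df$temperature_c,
             salinity = df$salinity_psu)
}

#' Write an environment CSV
#' @param env Data frame `year_ce`, `temperature`, `salinity`.
#' @param path Output path.
#' @export
write_env_csv <- function(env, path) {
  utils::write.csv(
    data.frame(year_ce = env$year_ce, temperature_c = env$temperature,
               salinity_psu = env$salinity),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a reconstruction result CSV
#' @param result A `reconstruction_result` from [reconstruct_ph()].
#' @param path Output path.
#' @export
write_reconstruction_csv <- function(result, path) {
  out <- data.frame(specimen_id = result$specimen_id,
                    year_ce = result$year_ce,
                    pH_median = result$ph_median,
                    ci68_lo = result$ci68_lo, ci68_hi = result$ci68_hi,
                    ci95_lo = result$ci95_lo, ci95_hi = result$ci95_hi,
                    n_valid_draws = result$n_valid_draws)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
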