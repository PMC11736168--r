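# Sclerochronology: calendar years from seasonal Mg/Ca cycles.
#
# The specimen surface is the collection year; each local summer maximum of
# the (smoothed, detrended) Mg/Ca transect marks one year of growth, counted
# backwards with increasing distance from the surface.

# Topographic prominence of local maxima (contour-walk definition): for each
# peak, the drop to the highest of the two key saddles separating it from
# higher terrain.
peak_prominence <- function(y, peaks) {
  n <- length(y)
  vapply(peaks, function(p) {
    # walk each side to the nearest point at or above the peak; the base
    # is the minimum on the way there
    higher_l <- which(y[seq_len(p - 1L)] >= y[p])
    from_l <- if (length(higher_l)) max(higher_l) + 1L else 1L
    base_l <- if (from_l <= p - 1L) min(y[from_l:(p - 1L)]) else NA_real_
    higher_r <- if (p < n) which(y[(p + 1L):n] >= y[p]) + p else integer(0)
    to_r <- if (length(higher_r)) min(higher_r) - 1L else n
    base_r <- if (p + 1L <= to_r) min(y[(p + 1L):to_r]) else NA_real_
    # a side that never rises back above the peak before the series ends
    # (a truncated outermost/innermost cycle) must not cap the prominence
    closed_l <- length(higher_l) > 0L
    closed_r <- length(higher_r) > 0L
    if (is.na(base_l)) base_l <- y[p]
    if (is.na(base_r)) base_r <- y[p]
    base <- if (closed_l && closed_r) max(base_l, base_r)
            else if (closed_l) base_l
            else if (closed_r) base_r
            else min(base_l, base_r)
    y[p] - base
  }, numeric(1))
}

# dominant cycle length (distance units) by periodogram of the series
# resampled to an even grid
dominant_cycle_length <- function(distance, mgca) {
  grid <- seq(min(distance), max(distance), length.out = length(distance))
  y <- stats::approx(distance, mgca, xout = grid)$y
  y <- y - stats::fitted(stats::lm(y ~ grid))
  sp <- stats::spec.pgram(stats::ts(y), plot = FALSE, detrend = FALSE,
                          taper = 0.1)
  f <- sp$freq[which.max(sp$spec)]  # cycles per sample
  (grid[2] - grid[1]) / f
}

#' Build an age model by counting seasonal Mg/Ca cycles
#'
#' Smooths the transect with a centred moving mean, removes a linear trend,
#' and takes local maxima with topographic prominence above a threshold as
#' annual (summer) anchors. Years are assigned backwards from
#' `collection_year`; the partial outermost band belongs to the collection
#' year. Deterministic: no randomness, no iterative refitting.
#'
#' @param transect Data frame with strictly increasing `distance_um` (um
#'   from the growth surface) and `mgca` (mmol/mol).
#' @param collection_year Integer year CE of collection (live-collected
#'   specimens: the surface is this year).
#' @param smoothing_window Moving-mean window, um; default 1/8 of the
#'   dominant cycle length estimated by periodogram.
#' @param min_prominence Prominence threshold in Mg/Ca units; default
#'   0.25 x IQR of the smoothed, detrended series.
#' @return An object of class `age_model`: list with `boundaries` (data
#'   frame `distance_um`, `year_ce`: the start-of-year anchor positions,
#'   years strictly decreasing with distance), `n_cycles`,
#'   `collection_year`, and the smoothing parameters used.
#' @export
count_cycles <- function(transect, collection_year,
                         smoothing_window = NULL, min_prominence = NULL) {
  stopifnot(all(c("distance_um", "mgca") %in% names(transect)))
  d <- transect$distance_um
  y <- transect$mgca
  if (length(d) < 6 || any(diff(d) <= 0)) {
    stop("transect needs >= 6 points with strictly increasing distance",
         call. = FALSE)
  }
  cyc <- dominant_cycle_length(d, y)
  if (is.null(smoothing_window)) smoothing_window <- cyc / 8
  step <- stats::median(diff(d))
  k <- max(1L, as.integer(round(smoothing_window / step)))
  if (k %% 2L == 0L) k <- k + 1L
  ys <- as.numeric(stats::filter(y, rep(1 / k, k), sides = 2))
  # pad the filter edges with the raw series
  ys[is.na(ys)] <- y[is.na(ys)]
  ys <- ys - stats::fitted(stats::lm(ys ~ d))
  if (is.null(min_prominence)) {
    min_prominence <- 0.25 * stats::IQR(ys)
  }
  if (diff(range(ys)) <= 1e-8 * max(1, abs(mean(y)))) {
    stop("insufficient signal: transect has no cyclic variability",
         call. = FALSE)
  }
  # collapse exact-tie plateaus so a flat-topped peak is one candidate
  runs <- rle(ys)
  yc <- runs$values
  run_end <- cumsum(runs$lengths)
  run_mid <- run_end - (runs$lengths - 1L) %/% 2L
  cand <- which(diff(sign(diff(yc))) < 0) + 1L
  if (length(cand) == 0) {
    stop("insufficient signal: no local maxima in smoothed transect",
         call. = FALSE)
  }
  prom <- peak_prominence(yc, cand)
  peaks_c <- cand[prom >= min_prominence]
  # a summer truncated by the growth surface still anchors the collection
  # year, provided the surface value reaches typical summer heights; a
  # record that merely starts declining began just after an unrecorded
  # summer. A rising tail at depth belongs to a summer the transect never
  # reached and is never counted.
  if (length(peaks_c) > 0 && yc[1] > yc[2] &&
      yc[1] >= min(yc[peaks_c]) - min_prominence / 4) {
    peaks_c <- c(1L, peaks_c)
  }
  if (length(peaks_c) < 2) {
    stop("insufficient signal: fewer than 2 seasonal cycles detected",
         call. = FALSE)
  }
  peaks <- run_mid[peaks_c]
  # each detected summer peak anchors one year, youngest nearest the surface
  boundaries <- data.frame(
    distance_um = d[peaks],
    year_ce = collection_year - seq_along(peaks) + 1L
  )
  structure(
    list(boundaries = boundaries, n_cycles = length(peaks),
         collection_year = as.integer(collection_year),
         smoothing_window = smoothing_window,
         min_prominence = min_prominence,
         transect_range = range(d)),
    class = "age_model"
  )
}

#' @export
print.age_model <- function(x, ...) {
  cat(sprintf("Mg/Ca age model: %d annual cycles, %d-%d CE\n",
              x$n_cycles, min(x$boundaries$year_ce), x$collection_year))
  cat(sprintf("  smoothing window %.1f um, prominence threshold %.3g\n",
              x$smoothing_window, x$min_prominence))
  invisible(x)
}

#' Map milled bands to calendar years via an age model
#'
#' Each band (an interval or a point position along the transect) is
#' assigned the year whose interval contains its midpoint; bands straddling
#' a year boundary take the interval with the larger overlap, ties going to
#' the younger year. Year intervals run from each annual anchor (inclusive,
#' younger side) to the next anchor; positions nearer the surface than the
#' first anchor belong to the collection year.
#'
#' @param records Data frame with `distance_um` (band midpoint, um) and
#'   optionally `width_um` (band extent; default 0 = point sample).
#' @param age_model An `age_model` from [count_cycles()].
#' @return `records` with an added integer `year_ce` column; out-of-range
#'   bands get `NA` with a warning.
#' @export
assign_years <- function(records, age_model) {
  stopifnot(inherits(age_model, "age_model"),
            "distance_um" %in% names(records))
  bd <- age_model$boundaries
  width <- if ("width_um" %in% names(records)) records$width_um else 0
  lo <- records$distance_um - width / 2
  hi <- records$distance_um + width / 2
  # year intervals along distance: [0, bd1] -> collection year, then
  # [bd_i, bd_{i+1}] -> year of anchor i, last anchor to end of transect ->
  # oldest year
  edges <- c(age_model$transect_range[1], bd$distance_um,
             age_model$transect_range[2])
  years <- c(age_model$collection_year, bd$year_ce)
  n_int <- length(years)
  year_ce <- rep(NA_integer_, nrow(records))
  in_range <- hi >= edges[1] & lo <= edges[n_int + 1]
  for (i in which(in_range)) {
    ov <- pmin(hi[i], edges[-1]) - pmax(lo[i], edges[-(n_int + 1)])
    ov <- pmax(ov, 0)
    if (all(ov == 0)) {
      # point sample: locate the containing interval
      j <- findInterval(records$distance_um[i], edges,
                        rightmost.closed = TRUE, all.inside = TRUE)
    } else {
      best <- max(ov)
      j <- which(ov >= best - 1e-9)[1]  # ties resolve to the younger year
    }
    year_ce[i] <- years[j]
  }
  if (any(!in_range)) {
    warning(sum(!in_range), " band(s) outside the transect range left ",
            "unmapped", call. = FALSE)
  }
  records$year_ce <- year_ce
  records
}
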