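# Event-aligned weather rate-of-change analysis: hourly differencing,
# +-7 h windows around stopover starts/ends, two-stage (stopover ->
# individual) averaging, loess smoothing, and peak-lag extraction.

#' Hourly change of a series
#'
#' First difference aligned to the later instant: `delta[t] = x[t] -
#' x[t-1]`; missing values propagate.
#'
#' @param x numeric vector sampled hourly.
#' @return numeric vector of the same length; first element NA.
#' @export
hourly_change <- function(x) {
  if (!length(x)) return(numeric(0))
  c(NA_real_, diff(x))
}

#' Extract a value window around an event
#'
#' Values of an hourly series at integer offsets `-before_h .. +after_h`
#' around `event_time` (rounded to the nearest hour first). Offsets outside
#' the series are NA.
#'
#' @param timestamps POSIXct vector of the hourly series.
#' @param values numeric vector, same length.
#' @param event_time POSIXct event instant.
#' @param before_h,after_h window half-widths in hours (defaults 7, 7).
#' @return numeric vector of length `before_h + after_h + 1`, named by
#'   offset.
#' @export
extract_event_window <- function(timestamps, values, event_time,
                                 before_h = 7, after_h = 7) {
  ev <- round(as.numeric(event_time) / 3600) * 3600
  offs <- seq(-before_h, after_h)
  want <- ev + offs * 3600
  pos <- match(want, as.numeric(timestamps))
  out <- rep(NA_real_, length(offs))
  ok <- !is.na(pos)
  out[ok] <- values[pos[ok]]
  names(out) <- offs
  out
}

#' Average event windows to the individual level
#'
#' Two-stage mean: per offset, stopover windows are first averaged within
#' each individual, then across individuals, so individuals with many
#' stopovers do not dominate. The 95 % interval per offset is the
#' individual-level mean +- 1.96 * sd/sqrt(n) across individuals (NA when
#' fewer than 2 individuals contribute).
#'
#' @param windows matrix, one row per stopover window (columns = offsets).
#' @param individuals character vector of individual ids, one per row.
#' @return an `aligned_change_curve` data frame: `offset_h`, `mean_change`,
#'   `ci_low`, `ci_high`, `n_individuals`.
#' @export
average_curves <- function(windows, individuals) {
  stopifnot(nrow(windows) == length(individuals), nrow(windows) >= 1)
  offs <- as.integer(colnames(windows))
  if (anyNA(offs)) offs <- seq_len(ncol(windows)) - 1L
  ids <- unique(individuals)
  ind_means <- t(vapply(ids, function(id) {
    w <- windows[individuals == id, , drop = FALSE]
    colMeans(w, na.rm = TRUE)
  }, numeric(ncol(windows))))
  ind_means[!is.finite(ind_means)] <- NA_real_
  m <- colMeans(ind_means, na.rm = TRUE)
  n_ind <- colSums(!is.na(ind_means))
  se <- apply(ind_means, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) >= 2) sd(v) / sqrt(length(v)) else NA_real_
  })
  out <- data.frame(
    offset_h = offs,
    mean_change = ifelse(n_ind > 0, m, NA_real_),
    ci_low = m - 1.96 * se,
    ci_high = m + 1.96 * se,
    n_individuals = n_ind
  )
  class(out) <- c("aligned_change_curve", "data.frame")
  out
}

#' Loess-smooth an aligned change curve
#'
#' Degree-2 local regression with tricube weights over the offsets. With
#' fewer than 5 finite points the curve is passed through unchanged with a
#' warning.
#'
#' @param curve an `aligned_change_curve`.
#' @param span loess span in (0, 1] (default 0.5).
#' @return the curve with a `smoothed` column.
#' @export
loess_smooth <- function(curve, span = 0.5) {
  stopifnot(span > 0, span <= 1)
  ok <- is.finite(curve$mean_change)
  if (sum(ok) < 5) {
    warning("fewer than 5 finite points; returning unsmoothed curve")
    curve$smoothed <- curve$mean_change
    return(curve)
  }
  fit <- loess(mean_change ~ offset_h, data = curve[ok, ],
               span = span, degree = 2,
               control = loess.control(surface = "direct"))
  sm <- rep(NA_real_, nrow(curve))
  sm[ok] <- predict(fit, newdata = curve$offset_h[ok])
  curve$smoothed <- sm
  curve
}

#' Lag of the peak rate of change relative to the event
#'
#' The offset of the extremum with the largest absolute smoothed change.
#' Ties break toward offset 0, then toward negative offsets. A peak at the
#' window edge is flagged as a boundary extremum.
#'
#' @param curve a smoothed `aligned_change_curve` (needs a `smoothed`
#'   column; falls back to `mean_change`).
#' @param event_kind `"start"` or `"end"`, recorded in the result.
#' @return a `peak_lag` list: `event_kind`, `lag_h`, `peak_sign`
#'   (`"max"`/`"min"`), `peak_value`, `boundary`.
#' @export
peak_lag <- function(curve, event_kind = c("start", "end")) {
  event_kind <- match.arg(event_kind)
  v <- if (!is.null(curve$smoothed)) curve$smoothed else curve$mean_change
  offs <- curve$offset_h
  ok <- is.finite(v)
  if (!any(ok)) stop("all-missing curve: no peak lag defined")
  av <- abs(v)
  mx <- max(av[ok])
  cand <- which(ok & av == mx)
  cand <- cand[order(abs(offs[cand]), offs[cand])]
  best <- cand[1]
  structure(list(event_kind = event_kind,
                 lag_h = offs[best],
                 peak_sign = if (v[best] >= 0) "max" else "min",
                 peak_value = v[best],
                 boundary = offs[best] %in% range(offs[ok])),
            class = "peak_lag")
}

#' Event-aligned weather analysis over a set of stopovers
#'
#' For each weather variable: difference the hourly series of each
#' migration track, window it around every stopover's start (or end),
#' average to the individual level, loess-smooth, and locate the peak rate
#' of change. Stopovers whose window contains any missing value are
#' counted as having incomplete weather.
#'
#' @param stopovers stopover data frame with `i1`, `i2`, `individual_id`
#'   and a `track_key` column naming which element of `rts` each belongs to.
#' @param rts named list of `regular_track`s with weather columns.
#' @param variables weather variable names (default: those on the first
#'   track).
#' @param event `"start"` or `"end"`.
#' @param before_h,after_h window half-widths (defaults 7).
#' @param span loess span (default 0.5).
#' @return list with `curves` (long data frame: variable, offset_h, mean,
#'   ci, smoothed), `lags` (one row per variable) and
#'   `n_incomplete_weather`.
#' @export
align_weather_events <- function(stopovers, rts, variables = NULL,
                                 event = c("start", "end"),
                                 before_h = 7, after_h = 7, span = 0.5) {
  event <- match.arg(event)
  stopifnot(nrow(stopovers) >= 1)
  if (is.null(variables)) variables <- weather_vars(rts[[1]])
  curves <- list(); lags <- list()
  incomplete <- rep(FALSE, nrow(stopovers))
  for (v in variables) {
    wins <- matrix(NA_real_, nrow(stopovers), before_h + after_h + 1)
    colnames(wins) <- seq(-before_h, after_h)
    for (k in seq_len(nrow(stopovers))) {
      rt <- rts[[stopovers$track_key[k]]]
      if (is.null(rt[[v]])) next
      dv <- hourly_change(rt[[v]])
      # differencing must not bridge interpolation segments
      if (any(rt$segment != rt$segment[1])) {
        dv[c(FALSE, diff(rt$segment) != 0)] <- NA_real_
      }
      ev_time <- if (event == "start") stopovers$start[k] else stopovers$end[k]
      wins[k, ] <- extract_event_window(rt$timestamp, dv, ev_time,
                                        before_h, after_h)
    }
    incomplete <- incomplete | apply(wins, 1, anyNA)
    cu <- average_curves(wins, stopovers$individual_id)
    cu <- loess_smooth(cu, span)
    pl <- peak_lag(cu, event)
    cu$variable <- v
    curves[[v]] <- cu
    lags[[v]] <- data.frame(variable = v, event_kind = event,
                            lag_h = pl$lag_h, peak_sign = pl$peak_sign,
                            peak_value = pl$peak_value,
                            boundary = pl$boundary,
                            stringsAsFactors = FALSE)
  }
  list(curves = do.call(rbind, c(curves, list(make.row.names = FALSE))),
       lags = do.call(rbind, c(lags, list(make.row.names = FALSE))),
       n_incomplete_weather = sum(incomplete))
}
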