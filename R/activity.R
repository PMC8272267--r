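# Per-stopover movement-activity summaries and the most-active-third
# exclusion used to strip likely foraging stopovers before the
# weather-alignment analysis.

#' Proportion of activity during stopovers
#'
#' For each stopover, daytime hours are the interval's fixes outside the
#' roosting window (default 08:00-17:00 local solar); active hours are
#' daytime fixes with speed strictly above `activity_kmh` (strict, so GPS
#' jitter at 1.0 km/h does not count as flight). `prop_activity` is the
#' active fraction of daytime hours; `total_distance_km` sums inter-fix
#' great-circle distances inside the interval.
#'
#' @param stopovers stopover data frame with `i1`, `i2` (from
#'   [segment_stopovers()] on the same track).
#' @param rt the `regular_track` the stopovers were detected on.
#' @param ctx a [solar_context()].
#' @param activity_kmh activity threshold in km/h (default 1; strict >).
#' @return the stopover data frame with `n_daytime_h`, `n_active_h`,
#'   `prop_activity` (NA, flagged in `activity_flag`, when there are no
#'   daytime hours) and `total_distance_km` appended.
#' @export
proportion_activity <- function(stopovers, rt, ctx = solar_context(),
                                activity_kmh = 1) {
  n <- nrow(stopovers)
  n_day <- integer(n); n_act <- integer(n)
  dist <- numeric(n); flag <- character(n)
  for (k in seq_len(n)) {
    ii <- stopovers$i1[k]:stopovers$i2[k]
    roost <- is_roost_hours(rt$timestamp[ii], rt$lon[ii], ctx)
    day_ii <- ii[!roost]
    n_day[k] <- length(day_ii)
    sp <- rt$speed_kmh[day_ii]
    n_act[k] <- sum(is.finite(sp) & sp > activity_kmh)
    steps <- ii[-length(ii)]
    dist[k] <- sum(rt$speed_kmh[steps], na.rm = TRUE)
    flag[k] <- if (n_day[k] == 0) "no_daytime_hours" else ""
  }
  stopovers$n_daytime_h <- n_day
  stopovers$n_active_h <- n_act
  stopovers$prop_activity <- ifelse(n_day > 0, n_act / n_day, NA_real_)
  stopovers$total_distance_km <- dist
  stopovers$activity_flag <- flag
  stopovers
}

#' Exclude the most active third of stopovers
#'
#' Sorts stopovers by decreasing `prop_activity` and removes the top third
#' (the stopovers most likely used for foraging rather than
#' weather-avoidance). Ties at the cut are broken by excluding higher
#' `total_distance_km` first, then earlier `start`.
#'
#' @param stopovers data frame with `prop_activity`, `total_distance_km`,
#'   `start` (>= 3 rows with defined `prop_activity`).
#' @param rounding `"ceiling"` (default) or `"floor"` for the size of the
#'   excluded third.
#' @return list with `retained` and `excluded` data frames.
#' @export
exclude_most_active_third <- function(stopovers, rounding = c("ceiling", "floor")) {
  rounding <- match.arg(rounding)
  ok <- is.finite(stopovers$prop_activity)
  if (sum(ok) < 3) stop("need at least 3 stopovers with defined prop_activity")
  df <- stopovers[ok, , drop = FALSE]
  ord <- order(-df$prop_activity, -df$total_distance_km,
               as.numeric(df$start))
  n <- nrow(df)
  k <- if (rounding == "ceiling") ceiling(n / 3) else floor(n / 3)
  excluded <- df[ord[seq_len(k)], , drop = FALSE]
  retained <- df[ord[-seq_len(k)], , drop = FALSE]
  retained <- retained[order(as.numeric(retained$start)), , drop = FALSE]
  excluded <- excluded[order(as.numeric(excluded$start)), , drop = FALSE]
  rownames(retained) <- rownames(excluded) <- NULL
  list(retained = retained, excluded = excluded,
       undefined = stopovers[!ok, , drop = FALSE])
}
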