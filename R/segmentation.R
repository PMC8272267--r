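# Turn FPT profiles into vetted stopover intervals: per-migration
# variance-based threshold, candidate runs, endpoint trimming, the
# roost-start rule, duration/daylight rejection, buffer rescue, merging.

#' Log-FPT threshold from the profile's mean and spread
#'
#' Classic mean + c*sd threshold on log FPT, computed per migration so
#' tracks with high FPT variance are not under-segmented nor low-variance
#' tracks over-segmented.
#'
#' @param profile an `fpt_profile`.
#' @param c multiplier on the sd (default 1).
#' @return threshold on the natural-log FPT scale.
#' @export
fpt_threshold <- function(profile, c = 1) {
  stopifnot(c >= 0)
  lf <- log(profile$fpt_h[is.finite(profile$fpt_h)])
  if (length(lf) < 2) stop("degenerate FPT profile: fewer than 2 finite FPTs")
  mean(lf) + c * sd(lf)
}

#' Between-class-variance (Otsu) log-FPT threshold
#'
#' Places the threshold where the split of log FPT values into a low
#' (transiting) and a high (restricted-movement) class maximises the
#' between-class variance; with the strongly bimodal profiles of directed
#' migration the threshold lands mid-gap between the flight mode and
#' everything slower, and is insensitive to how much of the track is spent
#' stopped. This is the default per-migration "threshold relative to the
#' variance of the FPT"; `fpt_threshold()` is available via config.
#'
#' @param profile an `fpt_profile`.
#' @return threshold on the natural-log FPT scale.
#' @export
fpt_threshold_otsu <- function(profile) {
  lf <- sort(log(profile$fpt_h[is.finite(profile$fpt_h)]))
  n <- length(lf)
  if (n < 2) stop("degenerate FPT profile: fewer than 2 finite FPTs")
  cs <- cumsum(lf)
  k <- seq_len(n - 1)
  m0 <- cs[k] / k
  m1 <- (cs[n] - cs[k]) / (n - k)
  bc <- (k / n) * ((n - k) / n) * (m0 - m1)^2
  ok <- lf[k + 1] > lf[k]
  bc[!ok] <- -Inf
  best <- which.max(bc)
  (lf[best] + lf[best + 1]) / 2
}

#' Candidate stopover runs above a log-FPT threshold
#'
#' Maximal runs of consecutive fixes with log FPT strictly above the
#' threshold; fixes with missing FPT break runs, as do segment boundaries.
#'
#' @param profile an `fpt_profile`.
#' @param threshold log-FPT threshold.
#' @param rt the `regular_track` the profile was computed on (for segment
#'   boundaries); optional, defaults to a single segment.
#' @return data frame with columns `i1`, `i2` (fix indices), `start`,
#'   `end` (POSIXct); zero rows when nothing is above threshold.
#' @export
detect_candidates <- function(profile, threshold, rt = NULL) {
  stopifnot(is.finite(threshold))
  above <- is.finite(profile$fpt_h) & log(profile$fpt_h) > threshold
  seg <- if (!is.null(rt)) rt$segment else rep(1L, length(above))
  n <- length(above)
  if (n == 0 || !any(above)) {
    return(data.frame(i1 = integer(), i2 = integer(),
                      start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC")))
  }
  brk <- c(TRUE, diff(seg) != 0 | diff(as.integer(above)) != 0)
  run_id <- cumsum(brk)
  idx <- seq_len(n)
  runs <- split(idx, run_id)
  runs <- runs[vapply(runs, function(ii) above[ii[1]], logical(1))]
  out <- data.frame(
    i1 = vapply(runs, function(ii) ii[1], integer(1)),
    i2 = vapply(runs, function(ii) ii[length(ii)], integer(1))
  )
  out$start <- profile$timestamp[out$i1]
  out$end <- profile$timestamp[out$i2]
  rownames(out) <- NULL
  out
}

#' Trim fast endpoints off a candidate interval
#'
#' Computes the 95th percentile (linear-interpolation sample quantile) of
#' the per-fix speeds inside the interval, then drops the first fix if its
#' speed strictly exceeds it and, independently, the last fix if its speed
#' does. Applied once, not iterated. This peels off the arrival/departure
#' flight step that FPT tends to absorb into the run.
#'
#' @param interval integer vector `c(i1, i2)` of fix indices (>= 3 fixes).
#' @param rt a `regular_track` with speeds attached.
#' @param prob quantile level (default 0.95).
#' @return adjusted `c(i1, i2)`.
#' @export
trim_endpoints <- function(interval, rt, prob = 0.95) {
  i1 <- interval[1]; i2 <- interval[2]
  stopifnot(i2 - i1 >= 2)
  sp <- rt$speed_kmh[i1:i2]
  q <- quantile(sp, prob, na.rm = TRUE, names = FALSE)
  if (is.finite(sp[1]) && sp[1] > q) i1 <- i1 + 1L
  sp_last <- rt$speed_kmh[i2]
  if (is.finite(sp_last) && sp_last > q) i2 <- i2 - 1L
  c(i1, i2)
}

#' Move a stopover start that follows an overnight cessation to 08:00
#'
#' If the bird ceased movement activity (speed <= `activity_kmh`) during
#' roosting hours, its true stopover start is ambiguous: overnight rest is
#' normal behaviour. The start is then moved to the roost-window end
#' (default 08:00 local solar) of the following morning. If that instant
#' falls at or beyond the interval end the interval is discarded (it was an
#' ordinary overnight roost). If the interval's first fix is itself active
#' (slow-movement stopover) no adjustment is made.
#'
#' @param interval integer vector `c(i1, i2)`.
#' @param rt a `regular_track` with speeds.
#' @param ctx a [solar_context()].
#' @param activity_kmh activity speed threshold (default 1 km/h).
#' @return adjusted `c(i1, i2)`, or NULL when discarded.
#' @export
roost_start_adjust <- function(interval, rt, ctx = solar_context(),
                               activity_kmh = 1) {
  i1 <- interval[1]; i2 <- interval[2]
  sp1 <- rt$speed_kmh[i1]
  if (is.finite(sp1) && sp1 > activity_kmh) return(c(i1, i2))
  seg_lo <- which(rt$segment == rt$segment[i1])[1]
  # cessation = first fix of the contiguous inactive run that contains i1
  cess <- i1
  while (cess > seg_lo) {
    spb <- rt$speed_kmh[cess - 1]
    if (is.finite(spb) && spb > activity_kmh) break
    cess <- cess - 1L
  }
  t_cess <- rt$timestamp[cess]
  if (!is_roost_hours(t_cess, rt$lon[cess], ctx)) return(c(i1, i2))
  h <- local_solar_hour(t_cess, rt$lon[cess])
  delta_h <- (ctx$roost_end_local - h) %% 24
  t_new <- t_cess + delta_h * 3600
  if (t_new >= rt$timestamp[i2]) return(NULL)
  i1_new <- which(rt$timestamp >= t_new & rt$segment == rt$segment[i2])[1]
  if (is.na(i1_new) || i1_new > i2) return(NULL)
  c(i1_new, i2)
}

#' Reject candidate intervals by duration and daylight coverage
#'
#' Drops intervals shorter than `min_duration_h` and intervals in which
#' fewer than `min_daylight_frac` of the fixes are during daylight
#' (sun above the official horizon): an interval made almost entirely of
#' night fixes is normal roosting, not a stopover.
#'
#' @param candidates data frame with `i1`, `i2`.
#' @param rt a `regular_track`.
#' @param min_duration_h minimum duration, hours (default 2).
#' @param min_daylight_frac minimum daylight fraction (default 0.25).
#' @return list with `kept` and `rejected` data frames; `rejected` has a
#'   `reason` column (`duration` or `daylight`).
#' @export
reject_filters <- function(candidates, rt, min_duration_h = 2,
                           min_daylight_frac = 0.25) {
  if (!nrow(candidates)) {
    return(list(kept = candidates,
                rejected = cbind(candidates, reason = character(0))))
  }
  dur <- as.numeric(rt$timestamp[candidates$i2]) -
    as.numeric(rt$timestamp[candidates$i1])
  dur <- dur / 3600
  dayfrac <- vapply(seq_len(nrow(candidates)), function(k) {
    ii <- candidates$i1[k]:candidates$i2[k]
    mean(is_daylight(rt$timestamp[ii], rt$lon[ii], rt$lat[ii]))
  }, numeric(1))
  reason <- rep(NA_character_, nrow(candidates))
  reason[dayfrac < min_daylight_frac] <- "daylight"
  reason[dur < min_duration_h] <- "duration"
  keep <- is.na(reason)
  kept <- candidates[keep, , drop = FALSE]
  rejected <- candidates[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  rownames(kept) <- rownames(rejected) <- NULL
  list(kept = kept, rejected = rejected)
}

#' Rescue slow, confined stopovers the FPT threshold missed
#'
#' Scans fixes not already inside kept intervals for maximal contiguous
#' runs in which every fix lies within `buffer_km` of the run's running
#' centroid; runs with strictly more than `min_points` fixes become
#' stopovers with provenance `"buffer"`. Catches fly-and-forage style
#' stopovers that drift too much for high FPT but stay in one neighbourhood.
#'
#' @param rt a `regular_track`.
#' @param kept_intervals data frame with `i1`, `i2` of already-kept
#'   stopovers (fixes inside them are skipped).
#' @param min_points strict minimum run size (default 30).
#' @param buffer_km buffer radius around the running centroid (default 15).
#' @return data frame with `i1`, `i2`, `start`, `end` of rescued runs.
#' @export
buffer_rescue <- function(rt, kept_intervals, min_points = 30,
                          buffer_km = 15) {
  stopifnot(min_points >= 1, buffer_km > 0)
  n <- nrow(rt)
  masked <- rep(FALSE, n)
  if (!is.null(kept_intervals) && nrow(kept_intervals)) {
    for (k in seq_len(nrow(kept_intervals))) {
      masked[kept_intervals$i1[k]:kept_intervals$i2[k]] <- TRUE
    }
  }
  out <- list()
  i <- 1L
  while (i <= n) {
    if (masked[i]) { i <- i + 1L; next }
    seg <- rt$segment[i]
    run <- i
    sum_lon <- rt$lon[i]; sum_lat <- rt$lat[i]
    j <- i + 1L
    while (j <= n && !masked[j] && rt$segment[j] == seg) {
      c_lon <- sum_lon / length(run); c_lat <- sum_lat / length(run)
      if (haversine_km(rt$lon[j], rt$lat[j], c_lon, c_lat) <= buffer_km) {
        run <- c(run, j)
        sum_lon <- sum_lon + rt$lon[j]; sum_lat <- sum_lat + rt$lat[j]
        j <- j + 1L
      } else break
    }
    if (length(run) > min_points) {
      out[[length(out) + 1]] <- data.frame(i1 = run[1], i2 = run[length(run)])
    }
    i <- j
  }
  if (!length(out)) {
    return(data.frame(i1 = integer(), i2 = integer(),
                      start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC")))
  }
  res <- do.call(rbind, out)
  res$start <- rt$timestamp[res$i1]
  res$end <- rt$timestamp[res$i2]
  res
}

# merge intervals whose gap is <= gap_h hours; provenance "fpt" dominates
.merge_intervals <- function(iv, rt, gap_h = 1) {
  if (nrow(iv) <= 1) return(list(merged = iv, n_merged = 0L))
  iv <- iv[order(iv$i1), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  n_merged <- 0L
  for (k in 2:nrow(iv)) {
    last <- nrow(out)
    gap <- (as.numeric(rt$timestamp[iv$i1[k]]) -
              as.numeric(rt$timestamp[out$i2[last]])) / 3600
    if (gap <= gap_h && rt$segment[iv$i1[k]] == rt$segment[out$i2[last]]) {
      out$i2[last] <- max(out$i2[last], iv$i2[k])
      if ("provenance" %in% names(out)) {
        out$provenance[last] <- if ("fpt" %in% c(out$provenance[last],
                                                 iv$provenance[k])) "fpt" else "buffer"
      }
      n_merged <- n_merged + 1L
    } else {
      out <- rbind(out, iv[k, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  list(merged = out, n_merged = n_merged)
}

#' Segment one migration into stopovers
#'
#' Full rule set: radius selection by maximal log-FPT variance, the
#' per-migration variance-based threshold, candidate runs, one-shot
#' endpoint trimming, the roost-start rule, duration and daylight
#' rejection, buffer rescue of slow confined stopovers, and merging of
#' intervals separated by at most the merge gap. Output intervals are
#' sorted, pairwise disjoint and at least `min_duration_h` long.
#'
#' @param rt a `regular_track` (one migration) with speeds attached.
#' @param config a [pipeline_config()].
#' @return a stopover data frame (`individual_id`, `population`, `season`,
#'   `start`, `end`, `duration_h`, `provenance`, `radius_m`, `lon`, `lat`,
#'   `i1`, `i2`) with a `report` attribute of stage counts.
#' @export
segment_stopovers <- function(rt, config = pipeline_config()) {
  ctx <- solar_context(config$roost_start_local, config$roost_end_local)
  report <- c(n_fixes = nrow(rt), candidates = 0L, discarded_roost = 0L,
              rejected_duration = 0L, rejected_daylight = 0L, kept_fpt = 0L,
              buffer_rescued = 0L, merged_away = 0L, final = 0L)
  empty <- data.frame(
    individual_id = character(), population = character(), season = character(),
    start = as.POSIXct(character(), tz = "UTC"),
    end = as.POSIXct(character(), tz = "UTC"),
    duration_h = numeric(), provenance = character(), radius_m = numeric(),
    lon = numeric(), lat = numeric(), i1 = integer(), i2 = integer(),
    stringsAsFactors = FALSE
  )
  if (is.null(rt$speed_kmh)) rt <- attach_speeds(rt)
  sel <- tryCatch(
    select_radius(rt, config$radius_min_m, config$radius_max_m,
                  config$radius_step_m),
    error = function(e) NULL
  )
  kept <- data.frame(i1 = integer(), i2 = integer())
  if (is.null(sel)) {
    warning("degenerate track: FPT undefined everywhere; no FPT stopovers")
    radius_m <- NA_real_
  } else {
    radius_m <- sel$chosen_radius_m
    prof <- sel$profile
    run_fpt <- is.finite(prof$log_var) && prof$log_var >= config$min_log_var
    if (run_fpt) {
      threshold <- switch(config$threshold_method,
        otsu = fpt_threshold_otsu(prof),
        mean_sd = fpt_threshold(prof, config$threshold_c),
        stop("unknown threshold_method: ", config$threshold_method)
      )
      cand <- detect_candidates(prof, threshold, rt)
      report["candidates"] <- nrow(cand)
      adj <- list()
      for (k in seq_len(nrow(cand))) {
        iv <- c(cand$i1[k], cand$i2[k])
        if (iv[2] - iv[1] >= 2) iv <- trim_endpoints(iv, rt)
        iv <- roost_start_adjust(iv, rt, ctx, config$activity_kmh)
        if (is.null(iv)) {
          report["discarded_roost"] <- report["discarded_roost"] + 1L
          next
        }
        adj[[length(adj) + 1]] <- data.frame(i1 = iv[1], i2 = iv[2])
      }
      if (length(adj)) {
        adj <- do.call(rbind, adj)
        rej <- reject_filters(adj, rt, config$min_duration_h,
                              config$min_daylight_frac)
        report["rejected_duration"] <- sum(rej$rejected$reason == "duration")
        report["rejected_daylight"] <- sum(rej$rejected$reason == "daylight")
        kept <- rej$kept
      }
      report["kept_fpt"] <- nrow(kept)
    }
  }
  kept$provenance <- rep("fpt", nrow(kept))
  resc <- buffer_rescue(rt, kept, config$buffer_min_points, config$buffer_km)
  report["buffer_rescued"] <- nrow(resc)
  if (nrow(resc)) {
    resc$provenance <- "buffer"
    all_iv <- rbind(kept[, c("i1", "i2", "provenance")],
                    resc[, c("i1", "i2", "provenance")])
  } else {
    all_iv <- kept[, intersect(c("i1", "i2", "provenance"), names(kept)),
                   drop = FALSE]
  }
  if (!nrow(all_iv)) {
    attr(empty, "report") <- report
    attr(empty, "radius_m") <- radius_m
    return(empty)
  }
  mg <- .merge_intervals(all_iv, rt, config$merge_gap_h)
  report["merged_away"] <- mg$n_merged
  iv <- mg$merged
  out <- data.frame(
    individual_id = attr(rt, "individual_id"),
    population = attr(rt, "population"),
    season = attr(rt, "season"),
    start = rt$timestamp[iv$i1],
    end = rt$timestamp[iv$i2],
    duration_h = (as.numeric(rt$timestamp[iv$i2]) -
                    as.numeric(rt$timestamp[iv$i1])) / 3600,
    provenance = iv$provenance,
    radius_m = ifelse(iv$provenance == "fpt", radius_m, NA_real_),
    lon = vapply(seq_len(nrow(iv)),
                 function(k) mean(rt$lon[iv$i1[k]:iv$i2[k]]), numeric(1)),
    lat = vapply(seq_len(nrow(iv)),
                 function(k) mean(rt$lat[iv$i1[k]:iv$i2[k]]), numeric(1)),
    i1 = iv$i1, i2 = iv$i2,
    stringsAsFactors = FALSE
  )
  report["final"] <- nrow(out)
  attr(out, "report") <- report
  attr(out, "radius_m") <- radius_m
  out
}
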