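# Synthetic migration world: correlated-random-walk tracks with diurnal
# flight and overnight roosting, precipitation-front events that ground the
# bird, optional slow foraging bouts, coupled hourly weather series, and
# the ground-truth stopover table that recovery tests score against.

#' Simulation configuration
#'
#' Defaults describe a mid-latitude soaring migrant: directed flight at
#' ~32 km/h during non-roost hours (08-17 local solar), overnight roosting,
#' migration legs of 1100-2600 km, fronts on ~22 % of days with durations
#' log-uniform between 2 h and 11 days (median ~23 h, so about half of all
#' stopovers last under a day), and weather with diurnal cycles plus
#' AR(1) noise whose precipitation ramp has its maximal hourly change
#' exactly at front onset.
#'
#' @param ... overrides of any default element.
#' @return a `sim_config` list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_individuals = 20,
    n_populations = 4,
    seasons = c("spring", "fall"),
    spring_start = "2018-03-18",
    fall_start = "2018-09-12",
    start_jitter_days = 5,
    # population start longitudes/latitudes (spring origin; fall reversed)
    pop_lon = c(-111, -99, -119, -63),
    pop_lat_south = c(29, 31, 33, -38),
    pop_lat_north = c(46, 50, 52, -22),
    leg_km_range = c(1100, 2600),
    cruise_kmh_mean = 32,
    cruise_kmh_sd = 4,
    heading_sd_deg = 8,
    roost_start_local = 17,
    roost_end_local = 8,
    front_daily_prob = 0.22,
    front_min_h = 2,
    front_max_h = 264,
    front_day_onset_prob = 0.8,
    front_onset_mean_h = 13.5,
    front_onset_sd_h = 2,
    front_gap_flight_h = 3,
    forced_immobility = TRUE,
    partial_speed_kmh = 4,
    forage_prob = 0.3,
    forage_duration_h = c(30, 50),
    forage_speed_kmh = c(2, 5),
    forage_radius_km = 5,
    jitter_sd_km = 0.03,
    horizon_days = 35,
    arrival_tail_h = 12,
    # activity-coupling truth for the binomial GLMM (published magnitudes)
    activity_betas = c(intercept = -1.7, precipitation_fraction = -3.8,
                       thermal_updraft_velocity = 9.2, temperature = 3.0),
    re_sd_population = 0.079,
    re_sd_individual = 0.079,
    temperature_anomaly_scale = 10,
    weather_params = NULL,
    seed = 42
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown sim_config field(s): ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  stopifnot(cfg$front_daily_prob >= 0, cfg$front_daily_prob <= 1,
            cfg$front_min_h >= 2, cfg$front_max_h >= cfg$front_min_h)
  class(cfg) <- "sim_config"
  cfg
}

#' Default weather-variable parameter table
#'
#' Mesor/amplitude/peak hour of the diurnal cycle, AR(1) noise, and the
#' front coupling per variable: `ramp` (precipitation rises with maximal
#' hourly change at onset), `suppress` (diurnal variable multiplied down
#' during the front), `add`/`subtract` (level shift), `none`.
#'
#' @return data frame, one row per weather variable.
#' @export
default_weather_params <- function() {
  data.frame(
    variable = c("downward_shortwave_radiation", "sensible_heat_flux",
                 "thermal_updraft_velocity", "total_atmospheric_water",
                 "precipitation_fraction", "boundary_height", "temperature",
                 "wind_speed", "surface_pressure",
                 "orographic_updraft_velocity"),
    mesor = c(320, 60, 1.1, 18, 0.04, 700, 15, 4, 1013, 0.3),
    amp = c(380, 90, 1.1, 1, 0, 600, 5, 1, 1, 0),
    peak_hour = c(13, 13, 14, 16, 12, 15, 15, 15, 16, 12),
    ar_phi = c(0.5, 0.5, 0.5, 0.8, 0.6, 0.6, 0.7, 0.6, 0.95, 0.5),
    ar_sd = c(25, 8, 0.07, 0.4, 0.02, 40, 0.4, 0.5, 0.3, 0.15),
    front = c("suppress", "suppress", "suppress", "add", "ramp", "suppress",
              "subtract", "add", "subtract", "none"),
    front_scale = c(0.8, 0.7, 0.9, 8, 0.65, 0.6, 4, 2, 3, 0),
    clip_lo = c(0, -50, 0, 0, 0, 50, -Inf, 0, -Inf, 0),
    clip_hi = c(Inf, Inf, Inf, Inf, 1, Inf, Inf, Inf, Inf, Inf),
    stringsAsFactors = FALSE
  )
}

# first instant >= t at which local solar hour enters the flight window
.next_flight_hour <- function(t, lon0, roost_start = 17, roost_end = 8) {
  h <- local_solar_hour(t, lon0)
  if (h >= roost_end && h < roost_start) return(t)
  delta <- (roost_end - h) %% 24
  t + delta * 3600
}

# per-migration front schedule; onset instants land on the hourly UTC grid
.schedule_fronts <- function(cfg, t0, lon0, n_hours) {
  fronts <- data.frame(t_on = as.POSIXct(character(), tz = "UTC"),
                       t_end = as.POSIXct(character(), tz = "UTC"),
                       duration_h = numeric(), onset_local_h = numeric())
  last_block <- as.POSIXct("1900-01-01", tz = "UTC")
  for (d in seq_len(cfg$horizon_days) - 1) {
    if (runif(1) >= cfg$front_daily_prob) next
    day_onset <- runif(1) < cfg$front_day_onset_prob
    o_loc <- if (day_onset) {
      min(16, max(9, round(rnorm(1, cfg$front_onset_mean_h,
                                 cfg$front_onset_sd_h))))
    } else {
      sample(17:23, 1)
    }
    dur <- round(exp(runif(1, log(cfg$front_min_h), log(cfg$front_max_h))))
    dur <- min(max(dur, cfg$front_min_h), cfg$front_max_h)
    t_on <- t0 + d * 86400 + round((o_loc - lon0 / 15) %% 24) * 3600
    t_end <- t_on + dur * 3600
    if (as.numeric(t_on - t0, units = "hours") >= n_hours - 2) next
    # require a clean flight gap after the previous front's resumption
    resume_prev <- .next_flight_hour(last_block, lon0,
                                     cfg$roost_start_local, cfg$roost_end_local)
    if (t_on < resume_prev + cfg$front_gap_flight_h * 3600) next
    fronts <- rbind(fronts, data.frame(t_on = t_on, t_end = t_end,
                                       duration_h = dur,
                                       onset_local_h = o_loc))
    last_block <- t_end
  }
  fronts
}

# AR(1) noise, deterministic under the ambient RNG state
.ar1 <- function(n, phi, sd) {
  as.numeric(stats::filter(rnorm(n, 0, sd), phi, method = "recursive"))
}

#' Simulate hourly weather series for every migration
#'
#' Each variable is a diurnal sinusoid (in mean local solar time of the
#' migration origin) plus AR(1) noise; during fronts precipitation ramps
#' up with its largest hourly increment exactly at front onset while
#' thermals, shortwave radiation, sensible heat flux and boundary height
#' are suppressed.
#'
#' @param config a [sim_config()].
#' @param seed integer; defaults to `config$seed`.
#' @return a `sim_weather` list with `meta` (one row per migration),
#'   `series` (list of hourly data frames) and `fronts` (list of front
#'   tables), plus the parameter table used.
#' @export
simulate_weather <- function(config = sim_config(), seed = config$seed) {
  set.seed(seed)
  cfg <- config
  wp <- if (is.null(cfg$weather_params)) default_weather_params() else cfg$weather_params
  pops <- paste0("pop", seq_len(cfg$n_populations))
  meta <- list(); series <- list(); fronts <- list()
  for (i in seq_len(cfg$n_individuals)) {
    pk <- ((i - 1) %% cfg$n_populations) + 1
    id <- sprintf("ind%02d", i)
    for (season in cfg$seasons) {
      north <- season == "spring"
      lat0 <- if (north) cfg$pop_lat_south[pk] else cfg$pop_lat_north[pk]
      lon0 <- cfg$pop_lon[pk] + runif(1, -2, 2)
      date0 <- as.Date(if (north) cfg$spring_start else cfg$fall_start) +
        sample(0:cfg$start_jitter_days, 1)
      t0 <- as.POSIXct(paste(date0, "00:00:00"), tz = "UTC")
      n_h <- cfg$horizon_days * 24
      tt <- t0 + (seq_len(n_h) - 1) * 3600
      fr <- .schedule_fronts(cfg, t0, lon0, n_h)
      # front-intensity curve shared by all coupled variables
      g <- numeric(n_h)
      if (nrow(fr)) {
        hrs <- as.numeric(tt)
        for (f in seq_len(nrow(fr))) {
          k_on <- (as.numeric(fr$t_on[f]) - as.numeric(t0)) / 3600 + 1
          k_end <- (as.numeric(fr$t_end[f]) - as.numeric(t0)) / 3600 + 1
          idx <- seq(max(1, k_on), min(n_h, k_end - 1))
          if (length(idx)) {
            g[idx] <- pmax(g[idx], 1 - 0.5^(idx - k_on + 1))
          }
          dec <- seq(min(n_h, k_end), min(n_h, k_end + 12))
          if (length(dec)) {
            g[dec] <- pmax(g[dec], (1 - 0.5^(k_end - k_on)) * 0.55^(dec - k_end + 1))
          }
        }
      }
      h_loc <- local_solar_hour(tt, lon0)
      ser <- data.frame(timestamp = tt)
      for (r in seq_len(nrow(wp))) {
        p <- wp[r, ]
        base <- p$mesor + p$amp * cos(2 * pi * (h_loc - p$peak_hour) / 24)
        noise <- .ar1(n_h, p$ar_phi, p$ar_sd)
        x <- switch(p$front,
          ramp = base + noise + p$front_scale * g,
          suppress = base * (1 - p$front_scale * g) + noise,
          add = base + noise + p$front_scale * g,
          subtract = base + noise - p$front_scale * g,
          none = base + noise
        )
        ser[[p$variable]] <- pmin(pmax(x, p$clip_lo), p$clip_hi)
      }
      key <- paste(id, season, sep = ".")
      meta[[key]] <- data.frame(
        key = key, individual_id = id, population = pops[pk],
        season = season, t0 = t0, lon0 = lon0, lat0 = lat0,
        heading = if (north) rnorm(1, 0, 4) else rnorm(1, 180, 4),
        leg_km = runif(1, cfg$leg_km_range[1], cfg$leg_km_range[2]),
        stringsAsFactors = FALSE
      )
      series[[key]] <- ser
      fronts[[key]] <- fr
    }
  }
  structure(list(meta = do.call(rbind, c(meta, list(make.row.names = FALSE))),
                 series = series, fronts = fronts, params = wp,
                 config = cfg, seed = seed),
            class = "sim_weather")
}

# destination of a flat-earth step (fine at hourly scale)
.step_dest <- function(lon, lat, bearing_deg, km) {
  b <- bearing_deg * pi / 180
  lat2 <- lat + km * cos(b) / 110.574
  lon2 <- lon + km * sin(b) / (111.320 * cos(lat * pi / 180))
  c(lon2, lat2)
}

.bearing_to <- function(lon1, lat1, lon2, lat2) {
  atan2((lon2 - lon1) * cos((lat1 + lat2) / 2 * pi / 180) * 111.320,
        (lat2 - lat1) * 110.574) * 180 / pi
}

#' Simulate tracks and ground-truth stopovers
#'
#' Hour-by-hour state machine per migration: directed correlated-walk
#' flight toward the migration heading during non-roost, non-front hours;
#' stationary (with GPS jitter) during roosts and fronts; optionally one
#' slow tortuous foraging bout confined to a small area. A ground-truth
#' stopover is any maximal period in which the bird fails to fly during
#' expected flight hours, from its first interrupted hour to the hour
#' directed flight actually resumes (spanning intervening roosts).
#'
#' @param config a [sim_config()].
#' @param weather a `sim_weather` from [simulate_weather()] (same config).
#' @param seed integer; defaults to `config$seed + 1`.
#' @return a `sim_tracks` list: `tracks` (list of `track` data frames with
#'   weather columns), `migrations` (table), `truth` (true stopovers with
#'   `cause`), `states` (per-hour behavioural states, for diagnostics),
#'   `n_censored` (truth bouts dropped because the track ended first).
#' @export
simulate_tracks <- function(config = sim_config(), weather = NULL,
                            seed = config$seed + 1) {
  cfg <- config
  if (is.null(weather)) weather <- simulate_weather(cfg)
  set.seed(seed)
  tracks <- list(); truths <- list(); migs <- list(); states_out <- list()
  n_censored <- 0L
  for (key in names(weather$series)) {
    m <- weather$meta[weather$meta$key == key, ]
    fr <- weather$fronts[[key]]
    ser <- weather$series[[key]]
    n_h <- nrow(ser)
    tt <- ser$timestamp
    # forage bout placement (clear of fronts, mid-migration)
    forage_win <- NULL
    if (runif(1) < cfg$forage_prob) {
      for (try in 1:20) {
        d <- sample(2:6, 1)
        o <- sample(9:12, 1)
        t_f <- m$t0 + d * 86400 + round((o - m$lon0 / 15) %% 24) * 3600
        dur <- round(runif(1, cfg$forage_duration_h[1], cfg$forage_duration_h[2]))
        t_fe <- t_f + dur * 3600
        clash <- FALSE
        if (nrow(fr)) {
          clash <- any(fr$t_on < t_fe + 3 * 3600 & fr$t_end > t_f - 3 * 3600)
        }
        if (!clash) { forage_win <- c(t_f, t_fe); break }
      }
    }
    lon <- m$lon0; lat <- m$lat0
    progress <- 0
    arrived_at <- NA_real_
    pos <- matrix(NA_real_, n_h, 2)
    state <- character(n_h)
    expected <- logical(n_h)
    anchor <- c(NA_real_, NA_real_)
    cut <- n_h
    for (i in seq_len(n_h)) {
      pos[i, ] <- c(lon, lat)
      t <- tt[i]
      roost <- is_roost_hours(t, lon, solar_context(cfg$roost_start_local,
                                                    cfg$roost_end_local))
      arrived <- !is.na(arrived_at)
      in_front <- nrow(fr) > 0 && any(t >= fr$t_on & t < fr$t_end)
      in_forage <- !is.null(forage_win) && t >= forage_win[1] && t < forage_win[2]
      expected[i] <- !roost && !arrived
      if (arrived) {
        state[i] <- "post"
        if (as.numeric(t) - arrived_at >= cfg$arrival_tail_h * 3600) {
          cut <- i; break
        }
      } else if (in_front && !roost) {
        state[i] <- "front"
        if (!cfg$forced_immobility) {
          dest <- .step_dest(lon, lat, runif(1, 0, 360),
                             cfg$partial_speed_kmh)
          lon <- dest[1]; lat <- dest[2]
        }
      } else if (roost) {
        state[i] <- if (in_front) "front" else "roost"
      } else if (in_forage) {
        state[i] <- "forage"
        if (is.na(anchor[1])) anchor <- c(lon, lat)
        sp <- runif(1, cfg$forage_speed_kmh[1], cfg$forage_speed_kmh[2])
        dest <- .step_dest(lon, lat, runif(1, 0, 360), sp)
        if (haversine_km(dest[1], dest[2], anchor[1], anchor[2]) >
            cfg$forage_radius_km) {
          dest <- .step_dest(lon, lat,
                             .bearing_to(lon, lat, anchor[1], anchor[2]), sp)
        }
        lon <- dest[1]; lat <- dest[2]
      } else {
        state[i] <- "fly"
        sp <- max(5, rnorm(1, cfg$cruise_kmh_mean, cfg$cruise_kmh_sd))
        b <- m$heading + rnorm(1, 0, cfg$heading_sd_deg)
        dest <- .step_dest(lon, lat, b, sp)
        lon <- dest[1]; lat <- dest[2]
        progress <- progress + sp
        if (progress >= m$leg_km) arrived_at <- as.numeric(t)
      }
    }
    idx <- seq_len(cut)
    jlon <- rnorm(cut, 0, cfg$jitter_sd_km / (111.32 * cos(pos[idx, 2] * pi / 180)))
    jlat <- rnorm(cut, 0, cfg$jitter_sd_km / 110.574)
    tr <- data.frame(
      individual_id = m$individual_id,
      population = m$population,
      timestamp = tt[idx],
      lon = pos[idx, 1] + jlon,
      lat = pos[idx, 2] + jlat,
      stringsAsFactors = FALSE
    )
    for (v in weather$params$variable) tr[[v]] <- ser[[v]][idx]
    st <- state[idx]; ex <- expected[idx]
    # ground truth from behaviour
    interrupted <- ex & st %in% c("front", "forage")
    truth <- list()
    if (any(interrupted)) {
      r <- rle(interrupted)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      runs <- data.frame(s = starts[r$values], e = ends[r$values])
      # merge bouts separated only by roost hours
      merged <- runs[1, , drop = FALSE]
      if (nrow(runs) > 1) {
        for (k in 2:nrow(runs)) {
          gap <- (merged$e[nrow(merged)] + 1):(runs$s[k] - 1)
          if (length(gap) && !any(ex[gap])) {
            merged$e[nrow(merged)] <- runs$e[k]
          } else {
            merged <- rbind(merged, runs[k, ])
          }
        }
      }
      for (k in seq_len(nrow(merged))) {
        after <- which(st == "fly" & seq_len(cut) > merged$e[k])
        if (!length(after)) { n_censored <- n_censored + 1L; next }
        resume <- after[1]
        in_fr <- FALSE
        if (nrow(fr)) {
          hrs <- tt[merged$s[k]:merged$e[k]]
          in_fr <- any(vapply(seq_len(nrow(fr)), function(f) {
            any(hrs >= fr$t_on[f] & hrs < fr$t_end[f])
          }, logical(1)))
        }
        truth[[length(truth) + 1]] <- data.frame(
          individual_id = m$individual_id, population = m$population,
          season = m$season, start = tt[merged$s[k]], end = tt[resume],
          duration_h = as.numeric(tt[resume] - tt[merged$s[k]], units = "hours"),
          cause = if (in_fr) "front" else "forage",
          stringsAsFactors = FALSE
        )
      }
    }
    tracks[[key]] <- tr
    states_out[[key]] <- data.frame(timestamp = tt[idx], state = st,
                                    expected_fly = ex)
    truths[[key]] <- if (length(truth)) do.call(rbind, truth) else NULL
    migs[[key]] <- data.frame(
      individual_id = m$individual_id, population = m$population,
      season = m$season, start = tt[1], end = tt[cut],
      stringsAsFactors = FALSE
    )
  }
  truth_list <- Filter(Negate(is.null), truths)
  truth_all <- if (length(truth_list)) {
    do.call(rbind, c(truth_list, list(make.row.names = FALSE)))
  } else NULL
  if (is.null(truth_all)) {
    truth_all <- data.frame(individual_id = character(), population = character(),
                            season = character(),
                            start = as.POSIXct(character(), tz = "UTC"),
                            end = as.POSIXct(character(), tz = "UTC"),
                            duration_h = numeric(), cause = character())
  }
  structure(list(tracks = tracks,
                 migrations = do.call(rbind, c(migs, list(make.row.names = FALSE))),
                 truth = truth_all, states = states_out,
                 n_censored = n_censored, config = cfg, seed = seed),
            class = "sim_tracks")
}

#' Simulate per-stopover activity outcomes from weather coupling
#'
#' For each true stopover, the per-hour probability of daytime movement
#' activity is `plogis(b0 + b_precip * precip + b_thermal * thermal +
#' b_temp * temp_anomaly)` with the stopover-mean covariates (temperature
#' enters as an anomaly from its mesor, divided by
#' `temperature_anomaly_scale`), plus Gaussian random intercepts for
#' population and individual-within-population; active hours are a
#' binomial draw over the stopover's daytime hours.
#'
#' @param truth truth table from [simulate_tracks()].
#' @param weather the matching `sim_weather`.
#' @param coupling_betas named numeric: intercept and the three slopes.
#' @param seed integer.
#' @param config the [sim_config()].
#' @return the truth table with `precipitation_fraction`,
#'   `thermal_updraft_velocity`, `temperature` (anomaly), `n_daytime_h`,
#'   `n_active_h`, `prop_activity` appended.
#' @export
simulate_activity_outcomes <- function(truth, weather,
                                       coupling_betas = NULL,
                                       seed = 99, config = weather$config) {
  cfg <- config
  if (is.null(coupling_betas)) coupling_betas <- cfg$activity_betas
  set.seed(seed)
  pops <- unique(weather$meta$population)
  inds <- unique(weather$meta$individual_id)
  u_pop <- setNames(rnorm(length(pops), 0, cfg$re_sd_population), pops)
  u_ind <- setNames(rnorm(length(inds), 0, cfg$re_sd_individual), inds)
  wp <- weather$params
  t_mesor <- wp$mesor[wp$variable == "temperature"]
  n <- nrow(truth)
  precip <- thermal <- temp <- nday <- nact <- numeric(n)
  for (k in seq_len(n)) {
    key <- paste(truth$individual_id[k], truth$season[k], sep = ".")
    ser <- weather$series[[key]]
    m <- weather$meta[weather$meta$key == key, ]
    ii <- ser$timestamp >= truth$start[k] & ser$timestamp < truth$end[k]
    precip[k] <- mean(ser$precipitation_fraction[ii])
    thermal[k] <- mean(ser$thermal_updraft_velocity[ii])
    temp[k] <- (mean(ser$temperature[ii]) - t_mesor) / cfg$temperature_anomaly_scale
    h <- local_solar_hour(ser$timestamp[ii], m$lon0)
    nday[k] <- sum(h >= cfg$roost_end_local & h < cfg$roost_start_local)
    eta <- coupling_betas[1] + coupling_betas[2] * precip[k] +
      coupling_betas[3] * thermal[k] + coupling_betas[4] * temp[k] +
      u_pop[truth$population[k]] + u_ind[truth$individual_id[k]]
    nact[k] <- rbinom(1, nday[k], plogis(eta))
  }
  truth$precipitation_fraction <- precip
  truth$thermal_updraft_velocity <- thermal
  truth$temperature <- temp
  truth$n_daytime_h <- as.integer(nday)
  truth$n_active_h <- as.integer(nact)
  truth$prop_activity <- ifelse(nday > 0, nact / nday, NA_real_)
  truth
}

#' Direct stopover-table generator for GLMM recovery studies
#'
#' Draws per-stopover mean-weather covariates on realistic scales
#' (precipitation fraction Beta-distributed; thermal updraft means around
#' 0.3 m/s, low because stopovers oversample suppressed weather;
#' temperature as a standardized anomaly), with a negative
#' precipitation-thermal correlation, then binomial activity outcomes
#' under the given coefficients and nested random intercepts.
#'
#' @param n_stopovers,n_individuals,n_populations design size.
#' @param betas numeric length 4: intercept, precip, thermal, temp.
#' @param re_sd_population,re_sd_individual random-intercept sds.
#' @param seed integer.
#' @return data frame ready for [fit_activity_glmm()].
#' @export
simulate_glmm_table <- function(n_stopovers = 460, n_individuals = 34,
                                n_populations = 4,
                                betas = c(-1.7, -3.8, 9.2, 3.0),
                                re_sd_population = 0.079,
                                re_sd_individual = 0.079,
                                seed = 1) {
  set.seed(seed)
  pops <- paste0("pop", seq_len(n_populations))
  inds <- sprintf("ind%02d", seq_len(n_individuals))
  ind_pop <- setNames(pops[((seq_len(n_individuals) - 1) %% n_populations) + 1],
                      inds)
  u_pop <- setNames(rnorm(n_populations, 0, re_sd_population), pops)
  u_ind <- setNames(rnorm(n_individuals, 0, re_sd_individual), inds)
  id <- sample(inds, n_stopovers, replace = TRUE)
  z <- rnorm(n_stopovers)
  precip <- qbeta(pnorm(0.6 * z + 0.8 * rnorm(n_stopovers)), 1.8, 5.5)
  thermal <- pmax(0, 0.3 - 0.07 * z + rnorm(n_stopovers, 0, 0.1))
  temp <- rnorm(n_stopovers, 0, 0.15)
  nday <- sample(4:40, n_stopovers, replace = TRUE)
  eta <- betas[1] + betas[2] * precip + betas[3] * thermal + betas[4] * temp +
    u_pop[ind_pop[id]] + u_ind[id]
  nact <- rbinom(n_stopovers, nday, plogis(eta))
  data.frame(
    individual_id = id, population = unname(ind_pop[id]),
    precipitation_fraction = precip, thermal_updraft_velocity = thermal,
    temperature = temp,
    n_daytime_h = nday, n_active_h = nact,
    stringsAsFactors = FALSE
  )
}

#' Thin a track to a longer mean fix interval
#'
#' Degrades a regular hourly track by random thinning (keeping first and
#' last fixes) so the hourly-interpolation stage has real work to do.
#'
#' @param track a `track`.
#' @param mean_interval_h target mean interval in hours.
#' @param seed integer.
#' @return thinned `track`.
#' @export
thin_track <- function(track, mean_interval_h = 2, seed = 1) {
  stopifnot(mean_interval_h >= 1)
  set.seed(seed)
  n <- nrow(track)
  keep <- runif(n) < 1 / mean_interval_h
  keep[c(1, n)] <- TRUE
  out <- track[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(track)
  out
}

#' Score detected stopovers against ground truth
#'
#' A detected stopover is a true positive when it overlaps a true stopover
#' of the same individual and season; recall is computed over true
#' stopovers of duration at least `min_true_duration_h`. Boundary errors
#' come from one-to-one best-overlap pairs between detections and the
#' scored truths.
#'
#' @param detected stopover data frame (`individual_id`, `season`,
#'   `start`, `end`).
#' @param truth truth table from [simulate_tracks()].
#' @param min_true_duration_h recall is scored over truths at least this
#'   long (default 3).
#' @return list: `precision`, `recall`, `boundary_err_h` (vector),
#'   `median_boundary_err_h`, `n_detected`, `n_true_scored`.
#' @export
evaluate_detection <- function(detected, truth, min_true_duration_h = 3) {
  ov_h <- function(a1, a2, b1, b2) {
    pmax(0, as.numeric(pmin(a2, b2)) - as.numeric(pmax(a1, b1))) / 3600
  }
  n_det <- nrow(detected)
  det_hit <- logical(n_det)
  scored <- truth[truth$duration_h >= min_true_duration_h, , drop = FALSE]
  tru_hit <- logical(nrow(scored))
  berr <- numeric(0)
  for (k in seq_len(n_det)) {
    same <- truth$individual_id == detected$individual_id[k] &
      truth$season == detected$season[k]
    if (any(same)) {
      o <- ov_h(detected$start[k], detected$end[k],
                truth$start[same], truth$end[same])
      det_hit[k] <- any(o > 0)
    }
  }
  if (nrow(scored)) {
    for (j in seq_len(nrow(scored))) {
      same <- detected$individual_id == scored$individual_id[j] &
        detected$season == scored$season[j]
      if (!any(same)) next
      o <- ov_h(scored$start[j], scored$end[j],
                detected$start[same], detected$end[same])
      if (any(o > 0)) {
        tru_hit[j] <- TRUE
        b <- which(same)[which.max(o)]
        berr <- c(berr,
                  abs(as.numeric(detected$start[b]) - as.numeric(scored$start[j])) / 3600,
                  abs(as.numeric(detected$end[b]) - as.numeric(scored$end[j])) / 3600)
      }
    }
  }
  list(precision = if (n_det) mean(det_hit) else NA_real_,
       recall = if (nrow(scored)) mean(tru_hit) else NA_real_,
       boundary_err_h = berr,
       median_boundary_err_h = if (length(berr)) median(berr) else NA_real_,
       n_detected = n_det, n_true_scored = nrow(scored))
}

#' Simulate a full dataset (weather + tracks + truth + activity)
#'
#' @param config a [sim_config()].
#' @return a `sim_dataset` list: `tracks`, `migrations`, `truth` (with
#'   activity outcomes), `weather`, `states`, `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  w <- simulate_weather(config)
  tr <- simulate_tracks(config, w)
  truth <- tr$truth
  if (nrow(truth)) {
    truth <- simulate_activity_outcomes(truth, w, seed = config$seed + 2)
  }
  structure(list(tracks = tr$tracks, migrations = tr$migrations,
                 truth = truth, weather = w, states = tr$states,
                 n_censored = tr$n_censored, config = config),
            class = "sim_dataset")
}

#' Write a simulated dataset as Movebank-dialect CSVs
#'
#' Emits `tracks.csv` (timestamp, location-long, location-lat,
#' individual-local-identifier, population, weather columns),
#' `migrations.csv` and `truth.csv` under `dir`.
#'
#' @param ds a `sim_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  all_tr <- do.call(rbind, c(ds$tracks, list(make.row.names = FALSE)))
  out <- data.frame(
    timestamp = .format_timestamps(all_tr$timestamp),
    `location-long` = all_tr$lon,
    `location-lat` = all_tr$lat,
    `individual-local-identifier` = all_tr$individual_id,
    population = all_tr$population,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  for (v in setdiff(names(all_tr),
                    c("timestamp", "lon", "lat", "individual_id", "population"))) {
    out[[v]] <- all_tr[[v]]
  }
  write.csv(out, file.path(dir, "tracks.csv"), row.names = FALSE)
  mg <- ds$migrations
  mg$start <- .format_timestamps(mg$start)
  mg$end <- .format_timestamps(mg$end)
  write.csv(mg, file.path(dir, "migrations.csv"), row.names = FALSE)
  th <- ds$truth
  if (nrow(th)) {
    th$start <- .format_timestamps(th$start)
    th$end <- .format_timestamps(th$end)
  }
  write.csv(th, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
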