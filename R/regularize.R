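# Hourly interpolation of irregular tracks, great-circle distances, speeds.

.EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance (haversine)
#'
#' Vectorised haversine distance on a sphere of radius 6371.0088 km.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees (WGS84).
#' @return distance in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  p <- pi / 180
  dlat <- (lat2 - lat1) * p
  dlon <- (lon2 - lon1) * p
  a <- sin(dlat / 2)^2 + cos(lat1 * p) * cos(lat2 * p) * sin(dlon / 2)^2
  a <- pmin(a, 1)
  2 * .EARTH_RADIUS_KM * asin(sqrt(a))
}

# Unwrap longitudes so consecutive differences never jump across the
# antimeridian; interpolation is then linear in the unwrapped coordinate.
.unwrap_lon <- function(lon) {
  if (length(lon) < 2) return(lon)
  d <- diff(lon)
  step <- numeric(length(d))
  step[d > 180] <- -360
  step[d < -180] <- 360
  lon + c(0, cumsum(step))
}

.wrap_lon <- function(lon) {
  w <- (lon + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

#' Interpolate a track to exact hourly fixes
#'
#' Positions (and weather covariates) are linearly interpolated in time to
#' every top-of-hour instant between the ceiling of the first fix and the
#' floor of the last. Longitudes are unwrapped before interpolation so
#' antimeridian crossings stay linear. Grid points that fall inside an
#' observation gap longer than `max_gap_h` are dropped and the output is
#' split into numbered segments; downstream operations never bridge
#' segments.
#'
#' @param track a `track` slice (>= 2 fixes) with optional `season`.
#' @param max_gap_h longest gap (hours) to interpolate across (default 24).
#' @return a `regular_track` data frame: `timestamp`, `lon`, `lat`,
#'   `interpolated` (no observation within 30 min), `segment`, weather
#'   columns; attributes `individual_id`, `population`, `season`.
#' @export
interpolate_hourly <- function(track, max_gap_h = 24) {
  stopifnot(nrow(track) >= 2)
  tt <- as.numeric(track$timestamp)
  first_h <- ceiling(tt[1] / 3600) * 3600
  last_h <- floor(tt[length(tt)] / 3600) * 3600
  if (last_h < first_h) {
    warning("track spans less than one hour; empty regular track")
    grid <- numeric(0)
  } else {
    grid <- seq(first_h, last_h, by = 3600)
  }
  lon_u <- .unwrap_lon(track$lon)
  wv <- weather_vars(track)
  if (length(grid)) {
    # locate each grid instant between observations
    idx <- findInterval(grid, tt, rightmost.closed = TRUE)
    idx <- pmin(pmax(idx, 1), length(tt) - 1)
    gap_h <- (tt[idx + 1] - tt[idx]) / 3600
    on_obs <- grid %in% tt
    keep <- on_obs | gap_h <= max_gap_h
    grid <- grid[keep]
  }
  if (!length(grid)) {
    out <- data.frame(timestamp = as.POSIXct(numeric(0), origin = "1970-01-01", tz = "UTC"),
                      lon = numeric(0), lat = numeric(0),
                      interpolated = logical(0), segment = integer(0))
  } else {
    lon_i <- approx(tt, lon_u, xout = grid, ties = "ordered")$y
    lat_i <- approx(tt, track$lat, xout = grid, ties = "ordered")$y
    # nearest-observation distance for the interpolation flag
    near <- vapply(grid, function(g) min(abs(tt - g)), numeric(1))
    seg <- cumsum(c(1L, as.integer(diff(grid) > 3600)))
    out <- data.frame(
      timestamp = as.POSIXct(grid, origin = "1970-01-01", tz = "UTC"),
      lon = .wrap_lon(lon_i), lat = lat_i,
      interpolated = near > 30 * 60,
      segment = seg
    )
    for (v in wv) {
      out[[v]] <- approx(tt, track[[v]], xout = grid, ties = "ordered")$y
    }
  }
  attr(out, "individual_id") <- track$individual_id[1]
  attr(out, "population") <- track$population[1]
  attr(out, "season") <- if (!is.null(track$season)) track$season[1] else NA_character_
  attr(out, "lon_unwrapped") <- if (length(grid)) .unwrap_lon(out$lon) else numeric(0)
  class(out) <- c("regular_track", "data.frame")
  out
}

#' Attach per-step speeds to a regular track
#'
#' `speed_kmh[i]` is the great-circle distance from fix i to fix i+1 over
#' one hour; NA at the last fix of each segment.
#'
#' @param rt a `regular_track`.
#' @return the same object with a `speed_kmh` column.
#' @export
attach_speeds <- function(rt) {
  n <- nrow(rt)
  sp <- rep(NA_real_, n)
  if (n >= 2) {
    d <- haversine_km(rt$lon[-n], rt$lat[-n], rt$lon[-1], rt$lat[-1])
    same_seg <- rt$segment[-n] == rt$segment[-1]
    sp[-n] <- ifelse(same_seg, d, NA_real_)
  }
  rt$speed_kmh <- sp
  rt
}

#' Total great-circle path length of a set of fixes, km
#' @param lon,lat coordinate vectors.
#' @return scalar km.
#' @export
path_length_km <- function(lon, lat) {
  n <- length(lon)
  if (n < 2) return(0)
  sum(haversine_km(lon[-n], lat[-n], lon[-1], lat[-1]))
}
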