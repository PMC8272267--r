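# Local solar time, NOAA solar position, daylight and roosting flags.

.d2r <- function(x) x * pi / 180
.r2d <- function(x) x * 180 / pi

# NOAA solar-position core: declination (deg) and equation of time (min)
# for POSIXct instants. Accuracy ~1 minute, ample for daylight flags.
.solar_core <- function(t) {
  jd <- as.numeric(t) / 86400 + 2440587.5
  jc <- (jd - 2451545) / 36525
  gmls <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  gmas <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  ecc <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  seqc <- sin(.d2r(gmas)) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(.d2r(2 * gmas)) * (0.019993 - 0.000101 * jc) +
    sin(.d2r(3 * gmas)) * 0.000289
  stl <- gmls + seqc
  sal <- stl - 0.00569 - 0.00478 * sin(.d2r(125.04 - 1934.136 * jc))
  moe <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  oc <- moe + 0.00256 * cos(.d2r(125.04 - 1934.136 * jc))
  decl <- .r2d(asin(sin(.d2r(oc)) * sin(.d2r(sal))))
  vary <- tan(.d2r(oc / 2))^2
  eqtime <- 4 * .r2d(
    vary * sin(2 * .d2r(gmls)) - 2 * ecc * sin(.d2r(gmas)) +
      4 * ecc * vary * sin(.d2r(gmas)) * cos(2 * .d2r(gmls)) -
      0.5 * vary^2 * sin(4 * .d2r(gmls)) -
      1.25 * ecc^2 * sin(2 * .d2r(gmas))
  )
  list(decl = decl, eqtime = eqtime)
}

#' Solar elevation angle
#'
#' @param t POSIXct (UTC), vectorised.
#' @param lon,lat degrees.
#' @return elevation above the horizon, degrees (no refraction correction;
#'   daylight tests use the standard -0.833 deg threshold instead).
#' @export
solar_elevation <- function(t, lon, lat) {
  sc <- .solar_core(t)
  mins <- (as.numeric(t) / 60) %% 1440
  tst <- (mins + sc$eqtime + 4 * lon) %% 1440
  ha <- tst / 4 - 180
  cz <- sin(.d2r(lat)) * sin(.d2r(sc$decl)) +
    cos(.d2r(lat)) * cos(.d2r(sc$decl)) * cos(.d2r(ha))
  90 - .r2d(acos(pmin(pmax(cz, -1), 1)))
}

#' Mean local solar time
#'
#' UTC shifted by lon/15 hours. Returned as POSIXct whose clock reading is
#' the local solar time (tz label stays UTC).
#'
#' @param t POSIXct (UTC).
#' @param lon degrees.
#' @return POSIXct.
#' @export
local_solar_time <- function(t, lon) {
  t + lon / 15 * 3600
}

#' Local solar hour of day (decimal)
#' @inheritParams local_solar_time
#' @return numeric in [0, 24).
#' @export
local_solar_hour <- function(t, lon) {
  (((as.numeric(t) / 3600) + lon / 15) %% 24)
}

#' Sunrise and sunset (NOAA approximation)
#'
#' @param lat,lon degrees.
#' @param date a `Date` (the local solar day).
#' @return list with `sunrise`, `sunset` (POSIXct UTC, NA under polar
#'   conditions) and `polar` in `"none"`, `"day"`, `"night"`.
#' @export
sunrise_sunset <- function(lat, lon, date) {
  noon_utc <- as.POSIXct(paste(date, "12:00:00"), tz = "UTC") - lon / 15 * 3600
  sc <- .solar_core(noon_utc)
  zen <- 90.833
  cos_ha <- (cos(.d2r(zen)) - sin(.d2r(lat)) * sin(.d2r(sc$decl))) /
    (cos(.d2r(lat)) * cos(.d2r(sc$decl)))
  if (cos_ha < -1) {
    return(list(sunrise = as.POSIXct(NA), sunset = as.POSIXct(NA), polar = "day"))
  }
  if (cos_ha > 1) {
    return(list(sunrise = as.POSIXct(NA), sunset = as.POSIXct(NA), polar = "night"))
  }
  ha <- .r2d(acos(cos_ha))
  day0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  sunrise <- day0 + (720 - 4 * (lon + ha) - sc$eqtime) * 60
  sunset <- day0 + (720 - 4 * (lon - ha) - sc$eqtime) * 60
  list(sunrise = sunrise, sunset = sunset, polar = "none")
}

#' Roosting-hour context
#'
#' The overnight roosting window in local solar hours, default 17:00-08:00.
#'
#' @param roost_start_local,roost_end_local hours of day in [0, 24).
#' @return a `solar_context` list.
#' @export
solar_context <- function(roost_start_local = 17, roost_end_local = 8) {
  stopifnot(roost_start_local >= 0, roost_start_local < 24,
            roost_end_local >= 0, roost_end_local < 24)
  structure(list(roost_start_local = roost_start_local,
                 roost_end_local = roost_end_local),
            class = "solar_context")
}

#' Is the sun up at these fixes?
#'
#' Daylight means the sun is above the standard official horizon
#' (elevation >= -0.833 deg, i.e. between local sunrise and sunset).
#'
#' @param t POSIXct (UTC), vectorised.
#' @param lon,lat degrees.
#' @return logical vector.
#' @export
is_daylight <- function(t, lon, lat) {
  solar_elevation(t, lon, lat) >= -0.833
}

#' Is this instant within roosting hours?
#'
#' Roosting hours use mean local solar time (longitude offset), not civil
#' time zones, because migrations cross zones.
#'
#' @param t POSIXct (UTC), vectorised.
#' @param lon degrees.
#' @param ctx a [solar_context()].
#' @return logical vector.
#' @export
is_roost_hours <- function(t, lon, ctx = solar_context()) {
  h <- local_solar_hour(t, lon)
  s <- ctx$roost_start_local
  e <- ctx$roost_end_local
  if (s > e) h >= s | h < e else h >= s & h < e
}
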