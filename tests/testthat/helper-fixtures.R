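# Fixture builders and independent oracles shared across test files.

UTC <- function(x) as.POSIXct(x, tz = "UTC")

# a regular_track built directly from vectors (already hourly)
make_rt <- function(timestamp, lon, lat, speeds = TRUE, segment = 1L, ...) {
  rt <- data.frame(timestamp = timestamp, lon = lon, lat = lat,
                   interpolated = FALSE,
                   segment = rep_len(segment, length(lon)))
  extra <- list(...)
  for (nm in names(extra)) rt[[nm]] <- extra[[nm]]
  attr(rt, "individual_id") <- "indA"
  attr(rt, "population") <- "popA"
  attr(rt, "season") <- "spring"
  class(rt) <- c("regular_track", "data.frame")
  if (speeds) rt <- attach_speeds(rt)
  rt
}

# straight eastward track at an exact ground speed (km/h) at the equator
make_line_rt <- function(n = 21, speed_kmh = 10,
                         t0 = UTC("2018-06-01 00:00:00")) {
  km_per_deg <- 6371.0088 * pi / 180
  lon <- (0:(n - 1)) * speed_kmh / km_per_deg
  make_rt(t0 + 3600 * (0:(n - 1)), lon, rep(0, n))
}

# two-mode track: directed legs interleaved with stationary bouts
make_two_mode_rt <- function(seed = 1, n = 60) {
  set.seed(seed)
  t0 <- UTC("2018-06-01 00:00:00")
  lon <- numeric(n); lat <- numeric(n)
  lon[1] <- -95; lat[1] <- 40
  moving <- TRUE
  for (i in 2:n) {
    if (i %% 15 == 0) moving <- !moving
    step <- if (moving) 25 else abs(rnorm(1, 0, 0.03))
    lat[i] <- lat[i - 1] + step / 110.574
    lon[i] <- lon[i - 1] + rnorm(1, 0, 0.002)
  }
  make_rt(t0 + 3600 * (0:(n - 1)), lon, lat)
}

# random mixed-behaviour track for oracle comparisons
make_rand_rt <- function(seed, n = 40) {
  set.seed(seed)
  t0 <- UTC("2018-06-01 00:00:00")
  lon <- numeric(n); lat <- numeric(n)
  lon[1] <- runif(1, -100, -90); lat[1] <- runif(1, 35, 45)
  mode <- "move"
  for (i in 2:n) {
    if (runif(1) < 0.15) mode <- if (mode == "move") "stay" else "move"
    step <- if (mode == "move") runif(1, 0.5, 8) else abs(rnorm(1, 0, 0.05))
    b <- runif(1, 0, 2 * pi)
    lat[i] <- lat[i - 1] + step * cos(b) / 110.574
    lon[i] <- lon[i - 1] + step * sin(b) / (111.32 * cos(lat[i - 1] * pi / 180))
  }
  make_rt(t0 + 3600 * (0:(n - 1)), lon, lat)
}

# independent brute-force FPT oracle: resample the lon/lat polyline at
# 1 s resolution and find the first radius exceedance on each side
fpt_oracle <- function(rt, radius_m) {
  tt <- as.numeric(rt$timestamp)
  s <- seq(tt[1], tt[length(tt)], by = 1)
  lon_s <- approx(tt, rt$lon, xout = s)$y
  lat_s <- approx(tt, rt$lat, xout = s)$y
  r_km <- radius_m / 1000
  vapply(seq_len(nrow(rt)), function(i) {
    d <- haversine_km(rt$lon[i], rt$lat[i], lon_s, lat_s)
    ti <- tt[i] - s[1] + 1
    out <- d > r_km
    fwd <- which(out & seq_along(s) > ti)[1]
    bwd_cand <- which(out & seq_along(s) < ti)
    bwd <- if (length(bwd_cand)) bwd_cand[length(bwd_cand)] else NA_integer_
    if (is.na(fwd) || is.na(bwd)) return(NA_real_)
    (s[fwd] - s[bwd]) / 3600
  }, numeric(1))
}

# a minimal fpt_profile object for threshold/candidate unit tests
make_profile <- function(log_fpt, t0 = UTC("2018-06-01 00:00:00")) {
  structure(list(radius_m = 3000, fpt_h = exp(log_fpt),
                 log_var = if (sum(is.finite(log_fpt)) >= 2) {
                   var(log_fpt[is.finite(log_fpt)])
                 } else NA_real_,
                 timestamp = t0 + 3600 * (seq_along(log_fpt) - 1)),
            class = "fpt_profile")
}

# run detection over every migration of a sim_tracks object
detect_all <- function(sim, pc = pipeline_config()) {
  out <- list()
  for (key in names(sim$tracks)) {
    t1 <- as_track(sim$tracks[[key]])
    t1$season <- sub(".*[.]", "", key)
    rt <- attach_speeds(interpolate_hourly(t1))
    so <- segment_stopovers(rt, pc)
    if (nrow(so)) { so$track_key <- key; out[[key]] <- so }
  }
  if (!length(out)) return(data.frame())
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

write_tmp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
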