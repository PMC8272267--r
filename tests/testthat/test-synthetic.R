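# synthetic_data: weather structure, track kinematics, truth, couplings.

test_that("weather is reproducible and reduces to pure sinusoids without noise", {
  cfg <- sim_config(n_individuals = 1, seasons = "spring", seed = 50)
  w1 <- simulate_weather(cfg)
  w2 <- simulate_weather(cfg)
  expect_identical(w1$series, w2$series)

  wp <- default_weather_params()
  wp$ar_sd <- 0
  cfg0 <- sim_config(n_individuals = 1, seasons = "spring",
                     front_daily_prob = 0, weather_params = wp, seed = 50)
  w0 <- simulate_weather(cfg0)
  ser <- w0$series[[1]]
  m <- w0$meta[1, ]
  h <- local_solar_hour(ser$timestamp, m$lon0)
  expected <- 15 + 5 * cos(2 * pi * (h - 15) / 24)  # temperature params
  expect_equal(ser$temperature, expected, tolerance = 1e-10)
  # discrete derivative of the sinusoid matches the hourly change
  expect_equal(hourly_change(ser$temperature)[-1], diff(expected),
               tolerance = 1e-10)
})

test_that("precipitation's largest hourly change falls exactly at front onset", {
  cfg <- sim_config(n_individuals = 4, seasons = "spring", seed = 51,
                    front_daily_prob = 0.5)
  w <- simulate_weather(cfg)
  checked <- 0
  for (key in names(w$series)) {
    fr <- w$fronts[[key]]
    ser <- w$series[[key]]
    dp <- hourly_change(ser$precipitation_fraction)
    for (f in seq_len(nrow(fr))) {
      k_on <- which(ser$timestamp == fr$t_on[f])
      if (!length(k_on)) next
      # largest change in a +-6 h neighbourhood sits at onset
      win <- max(2, k_on - 6):min(length(dp), k_on + 6)
      expect_equal(win[which.max(dp[win])], k_on)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 2)
})

test_that("tracks are deterministic; displacement matches cruise kinematics", {
  cfg <- sim_config(n_individuals = 1, seasons = "spring",
                    front_daily_prob = 0, forage_prob = 0,
                    jitter_sd_km = 0, seed = 52)
  w <- simulate_weather(cfg)
  s1 <- simulate_tracks(cfg, w)
  s2 <- simulate_tracks(cfg, w)
  expect_identical(s1$tracks, s2$tracks)
  tr <- s1$tracks[[1]]
  total <- path_length_km(tr$lon, tr$lat)
  m <- w$meta[1, ]
  expect_lt(abs(total - m$leg_km) / m$leg_km, 0.15)
  # day-scale displacement ~ cruise speed x 9 flight hours
  n_days <- as.numeric(diff(range(tr$timestamp)), units = "days")
  per_day <- total / n_days
  expect_gt(per_day, cfg$cruise_kmh_mean * 9 * 0.7)
  expect_lt(per_day, cfg$cruise_kmh_mean * 9 * 1.3)
})

test_that("truth durations span the stated range under the default world", {
  cfg <- sim_config(seed = 53)
  sim <- simulate_tracks(cfg, simulate_weather(cfg))
  expect_gt(nrow(sim$truth), 20)
  expect_true(all(sim$truth$duration_h >= 2))
  expect_lt(min(sim$truth$duration_h), 24)
  expect_gt(max(sim$truth$duration_h), 100)
  # non-overlapping per individual and season
  for (key in unique(paste(sim$truth$individual_id, sim$truth$season))) {
    d <- sim$truth[paste(sim$truth$individual_id, sim$truth$season) == key, ]
    d <- d[order(d$start), ]
    if (nrow(d) > 1) {
      expect_true(all(as.numeric(head(d$end, -1)) <=
                        as.numeric(tail(d$start, -1))))
    }
  }
})

test_that("activity outcomes: null coupling matches the intercept rate; monotone in thermal", {
  d0 <- simulate_glmm_table(n_stopovers = 3000, betas = c(-1, 0, 0, 0),
                            re_sd_population = 0, re_sd_individual = 0,
                            seed = 54)
  expect_lt(abs(mean(d0$n_active_h / d0$n_daytime_h) - plogis(-1)), 0.02)
  dT <- simulate_glmm_table(n_stopovers = 3000, betas = c(-1, 0, 9.2, 0),
                            seed = 55)
  hi <- dT$thermal_updraft_velocity > median(dT$thermal_updraft_velocity)
  expect_gt(mean(dT$n_active_h[hi] / dT$n_daytime_h[hi]),
            mean(dT$n_active_h[!hi] / dT$n_daytime_h[!hi]))
})

test_that("track-coupled activity outcomes are seed-reproducible", {
  cfg <- sim_config(n_individuals = 2, seasons = "spring", seed = 56)
  w <- simulate_weather(cfg)
  sim <- simulate_tracks(cfg, w)
  if (nrow(sim$truth)) {
    a1 <- simulate_activity_outcomes(sim$truth, w, seed = 7)
    a2 <- simulate_activity_outcomes(sim$truth, w, seed = 7)
    expect_identical(a1, a2)
    expect_true(all(a1$n_active_h <= a1$n_daytime_h))
  }
})

test_that("thin_track degrades the mean interval for the regularizer to fix", {
  cfg <- sim_config(n_individuals = 1, seasons = "spring", seed = 57)
  sim <- simulate_tracks(cfg, simulate_weather(cfg))
  tr <- as_track(sim$tracks[[1]])
  th <- thin_track(tr, 2, seed = 3)
  gaps <- diff(as.numeric(th$timestamp)) / 3600
  expect_gt(mean(gaps), 1.4)
  expect_lt(mean(gaps), 3)
  rt <- interpolate_hourly(th)
  expect_true(any(rt$interpolated))
  # interpolation restores the hourly grid
  expect_true(all(diff(as.numeric(rt$timestamp[rt$segment == 1])) == 3600))
})
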