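# stopover_segmentation: threshold, candidates, trim, roost rule,
# rejection filters, buffer rescue, and the composed segmenter.

test_that("fpt_threshold: hand-computed mean + c*sd cases", {
  p <- make_profile(c(0, 0, 0, 4, 4))
  expect_equal(fpt_threshold(p, 1), 1.6 + sqrt(4.8), tolerance = 1e-12)
  expect_equal(round(fpt_threshold(p, 1), 3), 3.791)
  expect_equal(fpt_threshold(p, 0), 1.6)
  pc <- make_profile(rep(2.5, 6))
  expect_equal(fpt_threshold(pc, 1), 2.5)
  expect_error(fpt_threshold(make_profile(c(1, NA, NA))), "degenerate")
})

test_that("fpt_threshold_otsu lands between well-separated modes", {
  p <- make_profile(c(rep(-1.5, 10), rep(2.7, 20), rep(4, 5)))
  th <- fpt_threshold_otsu(p)
  expect_gt(th, -1.5)
  expect_lt(th, 2.7)
})

test_that("detect_candidates: runs, breaks, fenceposts", {
  # nothing above threshold
  expect_equal(nrow(detect_candidates(make_profile(rep(0, 6)), 1)), 0)
  # one run of 5 hourly fixes -> one 4 h interval
  p <- make_profile(c(0, 0, 5, 5, 5, 5, 5, 0))
  cand <- detect_candidates(p, 3)
  expect_equal(nrow(cand), 1)
  expect_equal(as.numeric(cand$end - cand$start, units = "hours"), 4)
  # two runs separated by one sub-threshold fix
  p2 <- make_profile(c(5, 5, 0, 5, 5))
  expect_equal(nrow(detect_candidates(p2, 3)), 2)
  # missing FPT breaks runs
  p3 <- make_profile(c(5, 5, NA, 5, 5))
  expect_equal(nrow(detect_candidates(p3, 3)), 2)
})

test_that("trim_endpoints: 95th-percentile rule on constructed speed sets", {
  t0 <- UTC("2018-06-01 00:00:00")
  mk <- function(speeds) {
    rt <- make_rt(t0 + 3600 * (seq_along(speeds) - 1),
                  rep(0, length(speeds)), rep(0, length(speeds)),
                  speeds = FALSE)
    rt$speed_kmh <- speeds
    rt
  }
  # {40,1,1,1,1}: q95 = 32.2, first fix trimmed
  expect_equal(trim_endpoints(c(1, 5), mk(c(40, 1, 1, 1, 1))), c(2, 5))
  # all equal: nothing exceeds the quantile strictly
  expect_equal(trim_endpoints(c(1, 5), mk(rep(3, 5))), c(1, 5))
  # {1,1,1,1,50}: q95 = 40.2, last fix trimmed
  expect_equal(trim_endpoints(c(1, 5), mk(c(1, 1, 1, 1, 50))), c(1, 4))
})

# two-day hourly fixture at lon 0 whose speeds encode an activity cessation
make_cessation_rt <- function(stop_local_h, t_start = "2018-03-19 12:00:00",
                              n = 36) {
  t0 <- UTC(t_start)
  ts <- t0 + 3600 * (0:(n - 1))
  rt <- make_rt(ts, rep(0, n), rep(45, n), speeds = FALSE)
  rt$speed_kmh <- ifelse(ts < UTC(stop_local_h), 20, 0)
  rt
}

test_that("roost_start_adjust: the 0800 rule in its three canonical cases", {
  # cessation 19:00 (roost hours) -> start 08:00 next morning
  rt <- make_cessation_rt("2018-03-19 19:00:00")
  iv <- c(which(rt$timestamp == UTC("2018-03-19 19:00:00")),
          which(rt$timestamp == UTC("2018-03-20 18:00:00")))
  adj <- roost_start_adjust(iv, rt)
  expect_equal(rt$timestamp[adj[1]], UTC("2018-03-20 08:00:00"))
  expect_equal(adj[2], iv[2])

  # cessation 14:00 (not roost hours) -> unchanged
  rt2 <- make_cessation_rt("2018-03-19 14:00:00")
  iv2 <- c(which(rt2$timestamp == UTC("2018-03-19 14:00:00")),
           which(rt2$timestamp == UTC("2018-03-20 18:00:00")))
  expect_equal(roost_start_adjust(iv2, rt2), iv2)

  # cessation 07:00 (roost hours, pre-dawn) -> 08:00 the same morning
  rt3 <- make_cessation_rt("2018-03-20 07:00:00", "2018-03-20 00:00:00", 24)
  iv3 <- c(which(rt3$timestamp == UTC("2018-03-20 07:00:00")),
           which(rt3$timestamp == UTC("2018-03-20 20:00:00")))
  adj3 <- roost_start_adjust(iv3, rt3)
  expect_equal(rt3$timestamp[adj3[1]], UTC("2018-03-20 08:00:00"))

  # a pure overnight roost collapses (adjusted start >= end) -> discarded
  rt4 <- make_cessation_rt("2018-03-19 17:00:00")
  iv4 <- c(which(rt4$timestamp == UTC("2018-03-19 17:00:00")),
           which(rt4$timestamp == UTC("2018-03-20 07:00:00")))
  expect_null(roost_start_adjust(iv4, rt4))

  # slow-movement (active) stopover start is left alone
  rt5 <- make_cessation_rt("2018-03-21 00:00:00")  # always active
  rt5$speed_kmh[] <- 3
  iv5 <- c(5, 20)
  expect_equal(roost_start_adjust(iv5, rt5), iv5)
})

test_that("reject_filters: duration and daylight rules", {
  # 1.5 h candidate (half-hourly fixes) -> rejected for duration
  t0 <- UTC("2018-12-15 11:00:00")
  rt <- make_rt(t0 + 1800 * (0:3), rep(0, 4), rep(45, 4), speeds = FALSE)
  res <- reject_filters(data.frame(i1 = 1L, i2 = 4L), rt)
  expect_equal(nrow(res$kept), 0)
  expect_equal(res$rejected$reason, "duration")

  # 10 night fixes with 2 daylight (20 %) -> rejected for daylight
  # (lat 45, lon 0, mid-December: sunrise 07:31, sunset 16:19 UTC)
  rt2 <- make_rt(UTC("2018-12-15 00:00:00") + 3600 * (0:9),
                 rep(0, 10), rep(45, 10), speeds = FALSE)
  expect_equal(sum(is_daylight(rt2$timestamp, 0, 45)), 2)
  res2 <- reject_filters(data.frame(i1 = 1L, i2 = 10L), rt2)
  expect_equal(res2$rejected$reason, "daylight")

  # 10-fix, 9 h candidate with >= 25 % daylight -> kept
  rt3 <- make_rt(UTC("2018-12-15 03:00:00") + 3600 * (0:9),
                 rep(0, 10), rep(45, 10), speeds = FALSE)
  expect_equal(sum(is_daylight(rt3$timestamp, 0, 45)), 5)
  res3 <- reject_filters(data.frame(i1 = 1L, i2 = 10L), rt3)
  expect_equal(nrow(res3$kept), 1)
})

test_that("buffer_rescue: strict >30 points within 15 km of the running centroid", {
  t0 <- UTC("2018-06-01 00:00:00")
  no_kept <- data.frame(i1 = integer(), i2 = integer())
  set.seed(9)
  jit <- function(n) rnorm(n, 0, 1 / 111)  # ~1 km jitter
  # 31 confined fixes -> one rescue
  rt31 <- make_rt(t0 + 3600 * (0:30), -100 + jit(31), 40 + jit(31))
  expect_equal(nrow(buffer_rescue(rt31, no_kept)), 1)
  # exactly 30 -> none (strict >)
  rt30 <- make_rt(t0 + 3600 * (0:29), -100 + jit(30), 40 + jit(30))
  expect_equal(nrow(buffer_rescue(rt30, no_kept)), 0)
  # directed 20 km/h track exits the buffer -> none
  rt_dir <- make_rt(t0 + 3600 * (0:40), rep(-100, 41),
                    40 + (0:40) * 20 / 110.574)
  expect_equal(nrow(buffer_rescue(rt_dir, no_kept)), 0)
  # fixes inside kept intervals are skipped
  expect_equal(nrow(buffer_rescue(rt31, data.frame(i1 = 1L, i2 = 16L))), 0)
})

test_that("segment_stopovers: directed migration yields zero stopovers", {
  cfg <- sim_config(n_individuals = 1, seasons = "spring",
                    front_daily_prob = 0, forage_prob = 0, seed = 21)
  sim <- simulate_tracks(cfg, simulate_weather(cfg))
  det <- detect_all(sim)
  expect_equal(nrow(det), 0)
  expect_equal(nrow(sim$truth), 0)
})

test_that("segment_stopovers: an injected 48 h front is recovered within 1 h", {
  cfg <- sim_config(n_individuals = 1, seasons = "spring",
                    front_daily_prob = 0, forage_prob = 0, seed = 22)
  w <- simulate_weather(cfg)
  key <- names(w$series)[1]
  lon0 <- w$meta$lon0[1]; t0 <- w$meta$t0[1]
  t_on <- t0 + 2 * 86400 + round((11 - lon0 / 15) %% 24) * 3600
  w$fronts[[key]] <- data.frame(t_on = t_on, t_end = t_on + 48 * 3600,
                                duration_h = 48, onset_local_h = 11)
  sim <- simulate_tracks(cfg, w)
  expect_equal(nrow(sim$truth), 1)
  expect_equal(sim$truth$cause, "front")
  det <- detect_all(sim)
  expect_equal(nrow(det), 1)
  expect_lte(abs(as.numeric(det$start - sim$truth$start, units = "hours")), 1)
  expect_lte(abs(as.numeric(det$end - sim$truth$end, units = "hours")), 1)
})

test_that("segment_stopovers: forage bouts are recovered; outputs obey invariants", {
  cfg <- sim_config(n_individuals = 2, seasons = "fall",
                    front_daily_prob = 0.15, forage_prob = 1, seed = 23)
  sim <- simulate_tracks(cfg, simulate_weather(cfg))
  det <- detect_all(sim)
  expect_gt(nrow(det), 0)
  forage <- sim$truth[sim$truth$cause == "forage", ]
  for (j in seq_len(nrow(forage))) {
    hit <- det$individual_id == forage$individual_id[j] &
      det$start < forage$end[j] & det$end > forage$start[j]
    expect_true(any(hit))
  }
  # pairwise disjoint, >= 2 h, sorted per migration
  for (key in unique(det$track_key)) {
    d <- det[det$track_key == key, ]
    d <- d[order(d$start), ]
    expect_true(all(d$duration_h >= 2))
    if (nrow(d) > 1) {
      expect_true(all(as.numeric(head(d$end, -1)) <=
                        as.numeric(tail(d$start, -1))))
    }
  }
  # stage-count conservation and determinism
  key <- names(sim$tracks)[1]
  t1 <- as_track(sim$tracks[[key]]); t1$season <- "fall"
  rt <- attach_speeds(interpolate_hourly(t1))
  so1 <- segment_stopovers(rt)
  so2 <- segment_stopovers(rt)
  expect_identical(so1, so2)
  rep <- attr(so1, "report")
  expect_equal(rep[["candidates"]],
               rep[["discarded_roost"]] + rep[["rejected_duration"]] +
                 rep[["rejected_daylight"]] + rep[["kept_fpt"]])
})

test_that("fpt-provenance stopovers contain a fix above the migration threshold", {
  cfg <- sim_config(n_individuals = 1, seasons = "spring",
                    front_daily_prob = 0.5, seed = 31)
  sim <- simulate_tracks(cfg, simulate_weather(cfg))
  key <- names(sim$tracks)[1]
  t1 <- as_track(sim$tracks[[key]]); t1$season <- "spring"
  rt <- attach_speeds(interpolate_hourly(t1))
  so <- segment_stopovers(rt)
  fptso <- so[so$provenance == "fpt", ]
  expect_gte(nrow(fptso), 1)
  if (nrow(fptso)) {
    sel <- select_radius(rt)
    th <- fpt_threshold_otsu(sel$profile)
    for (k in seq_len(nrow(fptso))) {
      lf <- log(sel$profile$fpt_h[fptso$i1[k]:fptso$i2[k]])
      expect_true(any(lf > th, na.rm = TRUE))
    }
  }
})
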