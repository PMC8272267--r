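# track_model: Movebank reader, migration filtering, stopover CSV I/O.

test_that("read_movebank_csv handles identity, partitioning and dropped rows", {
  # one individual, three rows
  f1 <- write_tmp_csv(c(
    "timestamp,location-long,location-lat,individual-local-identifier",
    "2018-03-01 00:00:00.000,-100.0,40.0,A",
    "2018-03-01 01:00:00.000,-100.1,40.1,A",
    "2018-03-01 02:00:00.000,-100.2,40.2,A"
  ))
  tr <- read_movebank_csv(f1)
  expect_length(tr, 1)
  expect_equal(nrow(tr$A), 3)
  expect_s3_class(tr$A, "track")

  # two interleaved individuals, each sorted on output
  f2 <- write_tmp_csv(c(
    "timestamp,location-long,location-lat,individual-local-identifier",
    "2018-03-01 02:00:00,-100.2,40.2,B",
    "2018-03-01 00:00:00,-100.0,40.0,A",
    "2018-03-01 01:00:00,-100.1,40.1,B",
    "2018-03-01 01:00:00,-100.1,40.1,A"
  ))
  tr2 <- read_movebank_csv(f2)
  expect_setequal(names(tr2), c("A", "B"))
  expect_false(is.unsorted(tr2$A$timestamp))
  expect_false(is.unsorted(tr2$B$timestamp))

  # one blank latitude -> n-1 fixes, one logged drop
  f3 <- write_tmp_csv(c(
    "timestamp,location-long,location-lat,individual-local-identifier",
    "2018-03-01 00:00:00,-100.0,40.0,A",
    "2018-03-01 01:00:00,-100.1,,A",
    "2018-03-01 02:00:00,-100.2,40.2,A"
  ))
  expect_message(tr3 <- read_movebank_csv(f3), "dropped 1 rows")
  expect_equal(nrow(tr3$A), 2)
  expect_equal(attr(tr3, "dropped_rows"), 1)
})

test_that("reader errors name missing columns and bad timestamps", {
  f <- write_tmp_csv(c(
    "timestamp,location-long,individual-local-identifier",
    "2018-03-01 00:00:00,-100.0,A"
  ))
  expect_error(read_movebank_csv(f), "location-lat")
  f2 <- write_tmp_csv(c(
    "timestamp,location-long,location-lat,individual-local-identifier",
    "2018-03-01 00:00:00,-100.0,40.0,A",
    "not-a-time,-100.1,40.1,A"
  ))
  expect_error(read_movebank_csv(f2), "row 2")
})

test_that("extra numeric columns survive as weather covariates; column_map renames", {
  f <- write_tmp_csv(c(
    "time,lng,latd,bird,temperature",
    "2018-03-01 00:00:00,-100.0,40.0,A,11.5",
    "2018-03-01 01:00:00,-100.1,40.1,A,12.5"
  ))
  tr <- read_movebank_csv(f, column_map = c(
    timestamp = "time", `location-long` = "lng",
    `location-lat` = "latd", `individual-local-identifier` = "bird"
  ))
  expect_equal(weather_vars(tr$A), "temperature")
  expect_equal(tr$A$temperature, c(11.5, 12.5))
})

test_that("duplicate timestamps keep the first fix with a warning", {
  df <- data.frame(individual_id = "A",
                   timestamp = UTC("2018-03-01 00:00:00") + c(0, 0, 3600),
                   lon = c(1, 2, 3), lat = c(1, 2, 3))
  expect_warning(tr <- as_track(df), "duplicate")
  expect_equal(nrow(tr), 2)
  expect_equal(tr$lon[1], 1)
})

test_that("filter_regular_migrations applies the mean-interval rule", {
  t0 <- UTC("2018-03-01 00:00:00")
  mk <- function(gaps_h) {
    df <- data.frame(individual_id = "A",
                     timestamp = t0 + cumsum(c(0, gaps_h)) * 3600,
                     lon = seq(0, by = 0.1, length.out = length(gaps_h) + 1),
                     lat = 40)
    as_track(df)
  }
  mig <- data.frame(individual_id = "A", population = "p", season = "spring",
                    start = t0 - 3600, end = t0 + 40 * 3600)
  # hourly -> retained
  expect_length(filter_regular_migrations(list(mk(rep(1, 10))), mig), 1)
  # 6-hourly -> excluded
  expect_length(filter_regular_migrations(list(mk(rep(6, 5))), mig), 0)
  # gaps {1,1,10}: mean 4 -> excluded
  expect_length(filter_regular_migrations(list(mk(c(1, 1, 10))), mig), 0)
  # monotone in the threshold: larger threshold retains a superset
  small <- filter_regular_migrations(list(mk(c(1, 1, 10))), mig, 3)
  large <- filter_regular_migrations(list(mk(c(1, 1, 10))), mig, 5)
  expect_length(small, 0)
  expect_length(large, 1)
  # < 2 fixes -> warning, excluded
  one <- mk(1)
  mig2 <- data.frame(individual_id = "A", population = "p", season = "spring",
                     start = t0 + 7200, end = t0 + 9000)
  expect_warning(out <- filter_regular_migrations(list(one), mig2), "< 2 fixes")
  expect_length(out, 0)
})

test_that("stopover CSV round-trips losslessly", {
  so <- data.frame(
    individual_id = c("A", "B"), population = c("p1", "p2"),
    season = c("spring", "fall"),
    start = UTC("2018-03-02 05:00:00") + c(0, 86400),
    end = UTC("2018-03-02 11:00:00") + c(0, 86400),
    duration_h = c(6, 6), provenance = c("fpt", "buffer"),
    prop_activity = c(0.25, 0.5), total_distance_km = c(1.5, 30.2),
    stringsAsFactors = FALSE
  )
  f <- tempfile(fileext = ".csv")
  write_stopovers_csv(so, f)
  back <- read_stopovers_csv(f)
  expect_equal(back, so, ignore_attr = TRUE)
  # idempotent: writing the read-back gives identical bytes
  f2 <- tempfile(fileext = ".csv")
  write_stopovers_csv(back, f2)
  expect_identical(readLines(f), readLines(f2))
  # empty set -> header-only file
  f3 <- tempfile(fileext = ".csv")
  write_stopovers_csv(so[0, ], f3)
  expect_length(readLines(f3), 1)
})

test_that("displacement splitter finds the directed run of days", {
  t0 <- UTC("2018-03-01 12:00:00")
  n_days <- 8
  lat <- c(rep(30, 24), rep(30 + cumsum(rep(3 / 24, 24 * 4)), 1),
           rep(42, 24 * 3))  # 1 day resident, 4 days @ ~330 km/day, 3 resident
  ts <- t0 + 3600 * (seq_along(lat) - 1)
  tr <- as_track(data.frame(individual_id = "A", timestamp = ts,
                            lon = -100, lat = lat))
  mg <- split_migrations_by_displacement(tr, min_advance_km = 50)
  expect_equal(nrow(mg), 1)
  expect_lt(abs(as.numeric(mg$start - ts[25], units = "hours")), 36)
})
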