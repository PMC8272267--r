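# Track, migration and stopover I/O in the Movebank CSV dialect.

.movebank_cols <- c(
  timestamp = "timestamp",
  lon = "location-long",
  lat = "location-lat",
  id = "individual-local-identifier"
)

.parse_timestamps <- function(x) {
  t <- as.POSIXct(x, format = "%Y-%m-%d %H:%M:%OS", tz = "UTC")
  # fall back for timestamps without a seconds-fraction or without seconds
  miss <- is.na(t) & !is.na(x) & nzchar(x)
  if (any(miss)) {
    t[miss] <- as.POSIXct(x[miss], format = "%Y-%m-%d %H:%M", tz = "UTC")
  }
  t
}

.format_timestamps <- function(t) format(t, "%Y-%m-%d %H:%M:%S", tz = "UTC")

#' Construct a track
#'
#' A track is an ordered set of geographic fixes for one individual, held as
#' a data frame with columns `individual_id`, `population`, `timestamp`
#' (POSIXct, UTC), `lon`, `lat` and any number of numeric weather-covariate
#' columns. Fixes are sorted by time; duplicate timestamps keep the first
#' fix and drop the rest with a warning.
#'
#' @param df data frame with at least `individual_id`, `timestamp`, `lon`,
#'   `lat`; a `population` column is added (NA) if absent.
#' @return a `track` data frame.
#' @export
as_track <- function(df) {
  stopifnot(all(c("individual_id", "timestamp", "lon", "lat") %in% names(df)))
  if (!inherits(df$timestamp, "POSIXct")) {
    df$timestamp <- .parse_timestamps(as.character(df$timestamp))
  }
  attr(df$timestamp, "tzone") <- "UTC"
  if (is.null(df$population)) df$population <- NA_character_
  if (anyNA(df$timestamp)) stop("track has unparseable timestamps")
  bad <- df$lat < -90 | df$lat > 90 | df$lon <= -180 | df$lon > 180
  if (any(bad, na.rm = TRUE)) stop("track has coordinates outside WGS84 bounds")
  df <- df[order(df$timestamp), , drop = FALSE]
  dup <- duplicated(df$timestamp)
  if (any(dup)) {
    warning(sprintf("dropping %d duplicate-timestamp fixes (keeping first)",
                    sum(dup)))
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("track", "data.frame")
  df
}

#' Weather covariate column names of a track
#'
#' Any numeric column that is not a coordinate or bookkeeping column is
#' treated as a per-fix weather covariate.
#'
#' @param track a `track` or regular track data frame.
#' @return character vector of covariate names.
#' @export
weather_vars <- function(track) {
  reserved <- c("individual_id", "population", "season", "timestamp", "lon",
                "lat", "speed_kmh", "interpolated", "segment")
  nm <- setdiff(names(track), reserved)
  nm[vapply(track[nm], is.numeric, logical(1))]
}

#' Read tracks from a Movebank-style CSV
#'
#' Expects the Movebank dialect (`timestamp`, `location-long`,
#' `location-lat`, `individual-local-identifier`); nonstandard headers can
#' be renamed via `column_map`. Rows with missing coordinates are dropped
#' and counted; extra numeric columns are kept as weather covariates.
#'
#' @param path CSV file path.
#' @param column_map named character vector mapping standard names
#'   (`timestamp`, `location-long`, `location-lat`,
#'   `individual-local-identifier`, optionally `population`) to the actual
#'   headers in the file.
#' @return named list of `track` objects, one per individual, each carrying
#'   an attribute `dropped_rows` with the count of incomplete rows dropped.
#' @export
read_movebank_csv <- function(path, column_map = NULL) {
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  want <- .movebank_cols
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      if (column_map[[std]] %in% names(raw)) {
        names(raw)[names(raw) == column_map[[std]]] <- std
      }
    }
  }
  for (col in unname(want)) {
    if (!col %in% names(raw)) {
      stop(sprintf("missing mandatory column '%s' in %s", col, path))
    }
  }
  ts <- .parse_timestamps(raw[[want[["timestamp"]]]])
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1]
    stop(sprintf("unparseable timestamp at data row %d: '%s'",
                 bad, raw[[want[["timestamp"]]]][bad]))
  }
  lon <- as.numeric(raw[[want[["lon"]]]])
  lat <- as.numeric(raw[[want[["lat"]]]])
  keep <- !is.na(lon) & !is.na(lat)
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message(sprintf("read_movebank_csv: dropped %d rows with missing coordinates",
                    n_drop))
  }
  extra <- setdiff(names(raw), unname(want))
  df <- data.frame(
    individual_id = as.character(raw[[want[["id"]]]]),
    population = if ("population" %in% extra) {
      as.character(raw[["population"]])
    } else NA_character_,
    timestamp = ts, lon = lon, lat = lat,
    stringsAsFactors = FALSE
  )
  extra <- setdiff(extra, "population")
  for (col in extra) {
    v <- raw[[col]]
    if (is.numeric(v)) df[[col]] <- v
  }
  df <- df[keep, , drop = FALSE]
  out <- lapply(split(df, df$individual_id), function(d) {
    tr <- as_track(d)
    attr(tr, "dropped_rows") <- NA_integer_
    tr
  })
  # attribute the drop count to the list and to each track for auditability
  for (i in seq_along(out)) attr(out[[i]], "dropped_rows") <- n_drop
  attr(out, "dropped_rows") <- n_drop
  out
}

#' Read a migration table
#'
#' One row per migration: `individual_id`, `population`, `season`
#' (spring/fall), `start`, `end` (ISO 8601 UTC).
#'
#' @param path CSV file path.
#' @return data frame with POSIXct start/end.
#' @export
read_migrations_csv <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "season", "start", "end")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("migration table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(m$population)) m$population <- NA_character_
  m$start <- .parse_timestamps(m$start)
  m$end <- .parse_timestamps(m$end)
  if (any(m$start >= m$end)) stop("migration table has start >= end")
  m
}

#' Slice tracks to migrations with regular sampling
#'
#' Keeps only migration slices whose mean inter-fix interval is strictly
#' below `max_mean_interval_h` (irregular tracks make hourly interpolation
#' unreliable). Slices with fewer than 2 fixes are excluded with a warning.
#'
#' @param tracks list of `track` objects (as from [read_movebank_csv()]).
#' @param migrations migration table ([read_migrations_csv()]).
#' @param max_mean_interval_h regularity threshold in hours (default 3).
#' @return list of `list(track = <track slice>, migration = <row>)`.
#' @export
filter_regular_migrations <- function(tracks, migrations,
                                      max_mean_interval_h = 3) {
  stopifnot(max_mean_interval_h > 0)
  out <- list()
  for (k in seq_len(nrow(migrations))) {
    mg <- migrations[k, , drop = FALSE]
    tr <- NULL
    for (t in tracks) {
      if (t$individual_id[1] == mg$individual_id) { tr <- t; break }
    }
    if (is.null(tr)) next
    sl <- tr[tr$timestamp >= mg$start & tr$timestamp <= mg$end, , drop = FALSE]
    if (nrow(sl) < 2) {
      warning(sprintf("migration %s/%s has < 2 fixes; excluded",
                      mg$individual_id, mg$season))
      next
    }
    mean_gap_h <- mean(diff(as.numeric(sl$timestamp))) / 3600
    if (mean_gap_h >= max_mean_interval_h) next
    sl$season <- mg$season
    if (!is.na(mg$population)) sl$population <- mg$population
    rownames(sl) <- NULL
    class(sl) <- c("track", "data.frame")
    out[[length(out) + 1]] <- list(track = sl, migration = mg)
  }
  out
}

.stopover_csv_cols <- c("individual_id", "population", "season", "start",
                        "end", "duration_h", "provenance", "prop_activity",
                        "total_distance_km")

#' Write stopovers to CSV
#'
#' Columns: individual_id, population, season, start (ISO 8601 UTC), end,
#' duration_h, provenance, prop_activity, total_distance_km. Activity
#' columns are NA until [proportion_activity()] has been run.
#'
#' @param stopovers stopover data frame.
#' @param path output path.
#' @export
write_stopovers_csv <- function(stopovers, path) {
  df <- as.data.frame(stopovers)
  for (col in .stopover_csv_cols) {
    if (!col %in% names(df)) df[[col]] <- NA
  }
  df <- df[, .stopover_csv_cols, drop = FALSE]
  df$start <- .format_timestamps(df$start)
  df$end <- .format_timestamps(df$end)
  write.csv(df, path, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}

#' Read stopovers written by [write_stopovers_csv()]
#' @param path CSV path.
#' @return stopover data frame with POSIXct start/end.
#' @export
read_stopovers_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$start <- .parse_timestamps(df$start)
  df$end <- .parse_timestamps(df$end)
  df
}

#' Convenience net-displacement migration splitter
#'
#' Auxiliary stand-in for manual migration delineation: a migration is a
#' maximal run of days on each of which the great-circle displacement from
#' the track origin advances by more than `min_advance_km`. Not part of the
#' validated pipeline; real analyses should supply a curated migration
#' table.
#'
#' @param track a `track`.
#' @param min_advance_km minimum daily advance to count as a migration day.
#' @param min_days minimum run length in days.
#' @return migration table (possibly empty) with `individual_id`, `season`
#'   set to NA, `start`, `end`.
#' @export
split_migrations_by_displacement <- function(track, min_advance_km = 50,
                                             min_days = 2) {
  day <- as.Date(track$timestamp, tz = "UTC")
  days <- sort(unique(day))
  if (length(days) < 2) {
    return(data.frame(individual_id = character(), population = character(),
                      season = character(), start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC")))
  }
  disp <- vapply(days, function(d) {
    i <- max(which(day == d))
    haversine_km(track$lon[1], track$lat[1], track$lon[i], track$lat[i])
  }, numeric(1))
  adv <- c(disp[1], diff(disp)) > min_advance_km
  r <- rle(adv)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values & r$lengths >= min_days)
  out <- lapply(keep, function(k) {
    d0 <- days[starts[k]]; d1 <- days[ends[k]]
    data.frame(
      individual_id = track$individual_id[1],
      population = track$population[1],
      season = NA_character_,
      start = min(track$timestamp[day == d0]),
      end = max(track$timestamp[day == d1]),
      stringsAsFactors = FALSE
    )
  })
  if (!length(out)) {
    return(data.frame(individual_id = character(), population = character(),
                      season = character(), start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC")))
  }
  do.call(rbind, out)
}
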