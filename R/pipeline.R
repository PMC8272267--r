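# Pipeline orchestration: validated configuration, staged commands with
# run reports, and a small CLI front end.

.config_schema <- list(
  radius_min_m = function(x) is.numeric(x) && x > 0,
  radius_max_m = function(x) is.numeric(x) && x > 0,
  radius_step_m = function(x) is.numeric(x) && x > 0,
  threshold_method = function(x) is.character(x) && x %in% c("otsu", "mean_sd"),
  threshold_c = function(x) is.numeric(x) && x > 0,
  min_log_var = function(x) is.numeric(x) && x >= 0,
  min_duration_h = function(x) is.numeric(x) && x >= 0,
  min_daylight_frac = function(x) is.numeric(x) && x >= 0 && x <= 1,
  buffer_min_points = function(x) is.numeric(x) && x >= 1,
  buffer_km = function(x) is.numeric(x) && x > 0,
  activity_kmh = function(x) is.numeric(x) && x >= 0,
  roost_start_local = function(x) is.numeric(x) && x >= 0 && x < 24,
  roost_end_local = function(x) is.numeric(x) && x >= 0 && x < 24,
  merge_gap_h = function(x) is.numeric(x) && x >= 0,
  max_gap_h = function(x) is.numeric(x) && x > 0,
  max_mean_interval_h = function(x) is.numeric(x) && x > 0,
  window_before_h = function(x) is.numeric(x) && x >= 1,
  window_after_h = function(x) is.numeric(x) && x >= 1,
  loess_span = function(x) is.numeric(x) && x > 0 && x <= 1,
  cor_threshold = function(x) is.numeric(x) && x > 0 && x < 1,
  predictor_priority = function(x) is.character(x) && length(x) >= 1,
  exclude_rounding = function(x) is.character(x) && x %in% c("ceiling", "floor"),
  seed = function(x) is.numeric(x)
)

#' Pipeline configuration
#'
#' All tunable parameters of the detection and analysis stages, validated
#' against a schema. Defaults follow the fine-scale stopover protocol:
#' radius sweep 2500-6000 m by 250 m, per-migration between-class-variance
#' log-FPT threshold, 2 h minimum duration, 25 % daylight minimum,
#' strict >30 fixes / 15 km buffer rescue, >1 km/h activity, 17:00-08:00
#' local-solar roost window, +-7 h event windows, loess span 0.5 and a 0.6
#' correlation threshold for predictor pruning.
#'
#' @param ... overrides of any default field.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    radius_min_m = 2500, radius_max_m = 6000, radius_step_m = 250,
    threshold_method = "otsu", threshold_c = 1, min_log_var = 0.25,
    min_duration_h = 2, min_daylight_frac = 0.25,
    buffer_min_points = 30, buffer_km = 15,
    activity_kmh = 1,
    roost_start_local = 17, roost_end_local = 8,
    merge_gap_h = 1, max_gap_h = 24, max_mean_interval_h = 3,
    window_before_h = 7, window_after_h = 7, loess_span = 0.5,
    cor_threshold = 0.6,
    predictor_priority = c("thermal_updraft_velocity", "temperature",
                           "precipitation_fraction", "boundary_height",
                           "downward_shortwave_radiation",
                           "sensible_heat_flux", "total_atmospheric_water",
                           "wind_speed", "surface_pressure",
                           "orographic_updraft_velocity"),
    exclude_rounding = "ceiling",
    seed = 42
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  validate_config(cfg)
}

#' Validate a pipeline configuration against the schema
#' @param cfg a config list.
#' @return the config, classed `pipeline_config`; errors name the field.
#' @export
validate_config <- function(cfg) {
  for (field in names(.config_schema)) {
    if (is.null(cfg[[field]])) stop("config field missing: ", field)
    if (!.config_schema[[field]](cfg[[field]])) {
      stop("config field invalid: ", field)
    }
  }
  if (cfg$radius_min_m > cfg$radius_max_m) {
    stop("config field invalid: radius_min_m exceeds radius_max_m")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a JSON file
#' @param path JSON file of flat key/value pairs.
#' @return a validated `pipeline_config`.
#' @export
read_config_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

.log_stage <- function(...) message(sprintf(...))

#' Simulate a dataset to disk
#'
#' @param config a [pipeline_config()] (its `seed` drives the simulator).
#' @param out_dir output directory.
#' @param sim_overrides named list forwarded to [sim_config()].
#' @return output directory, invisibly.
#' @export
cmd_simulate <- function(config = pipeline_config(), out_dir,
                         sim_overrides = list()) {
  sc <- do.call(sim_config, c(list(seed = config$seed), sim_overrides))
  ds <- simulate_dataset(sc)
  write_sim_dataset(ds, out_dir)
  .log_stage("simulate: %d tracks, %d migrations, %d true stopovers -> %s",
             length(ds$tracks), nrow(ds$migrations), nrow(ds$truth), out_dir)
  invisible(out_dir)
}

# internal: regular tracks for every regular migration in a dataset dir
.prepare_regular_tracks <- function(config, data_dir) {
  tracks <- read_movebank_csv(file.path(data_dir, "tracks.csv"))
  migrations <- read_migrations_csv(file.path(data_dir, "migrations.csv"))
  slices <- filter_regular_migrations(tracks, migrations,
                                      config$max_mean_interval_h)
  rts <- list()
  for (s in slices) {
    rt <- interpolate_hourly(s$track, config$max_gap_h)
    if (!nrow(rt)) next
    rt <- attach_speeds(rt)
    key <- paste(s$migration$individual_id, s$migration$season, sep = ".")
    rts[[key]] <- rt
  }
  rts
}

#' Detect stopovers across a dataset
#'
#' Reads `tracks.csv` + `migrations.csv` from `data_dir`, regularises each
#' migration, segments stopovers, and writes `stopovers.csv` plus a
#' machine-readable `detect_report.json` with per-stage counts.
#'
#' @param config a [pipeline_config()].
#' @param data_dir input directory.
#' @param out_dir output directory (default `data_dir`).
#' @return stopover data frame (with `track_key`), invisibly.
#' @export
cmd_detect <- function(config = pipeline_config(), data_dir,
                       out_dir = data_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rts <- .prepare_regular_tracks(config, data_dir)
  all_st <- list(); reports <- list()
  for (key in names(rts)) {
    st <- segment_stopovers(rts[[key]], config)
    reports[[key]] <- as.list(attr(st, "report"))
    if (nrow(st)) {
      st$track_key <- key
      all_st[[key]] <- st
    }
  }
  stopovers <- if (length(all_st)) {
    do.call(rbind, c(all_st, list(make.row.names = FALSE)))
  } else {
    data.frame()
  }
  total <- Reduce(function(a, b) mapply(`+`, a, b, SIMPLIFY = FALSE),
                  reports)
  report <- list(per_migration = reports, total = total,
                 n_migrations = length(rts))
  jsonlite::write_json(report, file.path(out_dir, "detect_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (nrow(stopovers)) write_stopovers_csv(stopovers, file.path(out_dir, "stopovers.csv"))
  .log_stage("detect: %d stopovers from %d migrations",
             nrow(stopovers), length(rts))
  attr(stopovers, "report") <- report
  invisible(stopovers)
}

#' Activity metrics and most-active-third exclusion
#'
#' @param config a [pipeline_config()].
#' @param data_dir dataset directory.
#' @param stopovers stopover frame from [cmd_detect()] (recomputed if NULL).
#' @param out_dir output directory.
#' @return list with `stopovers` (activity columns appended and an
#'   `excluded_top_third` flag), written to `stopovers_activity.csv`.
#' @export
cmd_activity <- function(config = pipeline_config(), data_dir,
                         stopovers = NULL, out_dir = data_dir) {
  if (is.null(stopovers)) stopovers <- cmd_detect(config, data_dir, out_dir)
  if (!nrow(stopovers)) return(invisible(list(stopovers = stopovers)))
  rts <- .prepare_regular_tracks(config, data_dir)
  ctx <- solar_context(config$roost_start_local, config$roost_end_local)
  out <- list()
  for (key in unique(stopovers$track_key)) {
    sub <- stopovers[stopovers$track_key == key, , drop = FALSE]
    out[[key]] <- proportion_activity(sub, rts[[key]], ctx, config$activity_kmh)
  }
  st <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  spl <- exclude_most_active_third(st, config$exclude_rounding)
  st$excluded_top_third <- FALSE
  key_of <- function(d) paste(d$track_key, as.numeric(d$start))
  st$excluded_top_third[key_of(st) %in% key_of(spl$excluded)] <- TRUE
  csv <- st
  csv$start <- .format_timestamps(csv$start)
  csv$end <- .format_timestamps(csv$end)
  write.csv(csv, file.path(out_dir, "stopovers_activity.csv"),
            row.names = FALSE)
  .log_stage("activity: %d stopovers, %d excluded as most-active third",
             nrow(st), sum(st$excluded_top_third))
  invisible(list(stopovers = st, split = spl))
}

#' Event-aligned weather curves and peak lags
#'
#' Runs the +-7 h rate-of-change analysis around stopover starts and ends
#' for the retained (not most-active-third) stopovers; writes
#' `curves.csv` and `lags.csv`.
#'
#' @param config a [pipeline_config()].
#' @param data_dir dataset directory.
#' @param activity result of [cmd_activity()] (recomputed if NULL).
#' @param out_dir output directory.
#' @return list with `start`, `end` alignment results, invisibly.
#' @export
cmd_align <- function(config = pipeline_config(), data_dir,
                      activity = NULL, out_dir = data_dir) {
  if (is.null(activity)) activity <- cmd_activity(config, data_dir, out_dir = out_dir)
  st <- activity$stopovers
  st <- st[!st$excluded_top_third, , drop = FALSE]
  if (!nrow(st)) {
    .log_stage("align: no retained stopovers")
    return(invisible(NULL))
  }
  rts <- .prepare_regular_tracks(config, data_dir)
  res <- list()
  for (ev in c("start", "end")) {
    res[[ev]] <- align_weather_events(
      st, rts, event = ev,
      before_h = config$window_before_h, after_h = config$window_after_h,
      span = config$loess_span
    )
  }
  curves <- rbind(cbind(res$start$curves, event_kind = "start"),
                  cbind(res$end$curves, event_kind = "end"))
  lags <- rbind(res$start$lags, res$end$lags)
  write.csv(curves, file.path(out_dir, "curves.csv"), row.names = FALSE)
  write.csv(lags, file.path(out_dir, "lags.csv"), row.names = FALSE)
  .log_stage("align: %d stopovers, %d with incomplete weather windows",
             nrow(st), res$start$n_incomplete_weather)
  invisible(res)
}

#' Fit the two inferential models over a dataset
#'
#' Stopover counts per migration (Gaussian LMM) and the binomial activity
#' GLMM on pruned mean-weather predictors; writes `count_model.csv` and
#' `activity_model.csv`.
#'
#' @param config a [pipeline_config()].
#' @param data_dir dataset directory.
#' @param activity result of [cmd_activity()] (recomputed if NULL).
#' @param out_dir output directory.
#' @return list with both fitted results, invisibly.
#' @export
cmd_models <- function(config = pipeline_config(), data_dir,
                       activity = NULL, out_dir = data_dir) {
  if (is.null(activity)) activity <- cmd_activity(config, data_dir, out_dir = out_dir)
  st <- activity$stopovers
  migrations <- read_migrations_csv(file.path(data_dir, "migrations.csv"))
  counts <- migrations
  key <- paste(counts$individual_id, counts$season, sep = ".")
  counts$count <- vapply(key, function(k) sum(st$track_key == k), numeric(1))
  cm <- fit_stopover_count_model(counts)
  write.csv(coef_table(cm), file.path(out_dir, "count_model.csv"),
            row.names = FALSE)
  rts <- .prepare_regular_tracks(config, data_dir)
  wv <- weather_vars(rts[[1]])
  for (v in wv) {
    st[[paste0("mean_", v)]] <- vapply(seq_len(nrow(st)), function(k) {
      rt <- rts[[st$track_key[k]]]
      mean(rt[[v]][st$i1[k]:st$i2[k]], na.rm = TRUE)
    }, numeric(1))
  }
  pred_cols <- paste0("mean_", config$predictor_priority)
  pred_cols <- pred_cols[pred_cols %in% names(st)]
  retained <- prune_correlated_predictors(st[, pred_cols, drop = FALSE],
                                          pred_cols, config$cor_threshold)
  am <- tryCatch(fit_activity_glmm(st, retained), error = function(e) e)
  if (inherits(am, "error")) {
    .log_stage("models: activity GLMM failed: %s", conditionMessage(am))
  } else {
    write.csv(coef_table(am), file.path(out_dir, "activity_model.csv"),
              row.names = FALSE)
  }
  .log_stage("models: count LMM on %d migrations; GLMM predictors: %s",
             nrow(counts), paste(retained, collapse = ", "))
  invisible(list(count_model = cm, activity_model = am,
                 retained_predictors = retained))
}

#' Run the whole pipeline on a synthetic dataset
#'
#' simulate -> detect -> activity -> align -> models, with a consolidated
#' `run_report.json` of per-stage counts so the bookkeeping (candidates,
#' rejections, rescues, exclusions, incomplete weather) is auditable.
#'
#' @param config a [pipeline_config()].
#' @param out_dir working directory for all inputs/outputs.
#' @param sim_overrides named list forwarded to [sim_config()].
#' @return list of stage results, invisibly.
#' @export
cmd_all <- function(config = pipeline_config(), out_dir,
                    sim_overrides = list()) {
  cmd_simulate(config, out_dir, sim_overrides)
  st <- cmd_detect(config, out_dir)
  act <- cmd_activity(config, out_dir, stopovers = st)
  al <- cmd_align(config, out_dir, activity = act)
  md <- tryCatch(cmd_models(config, out_dir, activity = act),
                 error = function(e) {
                   .log_stage("models stage failed: %s", conditionMessage(e))
                   NULL
                 })
  report <- list(
    detect = attr(st, "report")$total,
    n_stopovers = nrow(st),
    n_excluded_top_third = if (!is.null(act$stopovers)) {
      sum(act$stopovers$excluded_top_third)
    } else 0,
    n_incomplete_weather_start = if (!is.null(al)) {
      al$start$n_incomplete_weather
    } else NA,
    seed = config$seed
  )
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(stopovers = st, activity = act, align = al, models = md,
                 report = report))
}

#' Command-line entry point
#'
#' Subcommands `simulate`, `detect`, `activity`, `align`, `models`, `all`;
#' flags `--config <json>`, `--seed <int>`, `--data <dir>`, `--out <dir>`,
#' `--radius-min`, `--radius-max`, `--radius-step`, `--threshold-c`,
#' `--span`. Flags override config-file values.
#'
#' @param args character vector (default: the command line).
#' @return exit status 0 invisibly; stops with a message on bad usage.
#' @export
fptstop_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: fptstop <simulate|detect|activity|align|models|all> [flags]")
  cmd <- args[1]
  flags <- list()
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (i + 1 > length(args)) stop("flag without value: --", key)
    flags[[key]] <- args[i + 1]
    i <- i + 2
  }
  cfg <- if (!is.null(flags$config)) read_config_json(flags$config) else pipeline_config()
  num_flags <- c(`radius-min` = "radius_min_m", `radius-max` = "radius_max_m",
                 `radius-step` = "radius_step_m", `threshold-c` = "threshold_c",
                 span = "loess_span", seed = "seed")
  for (fl in names(num_flags)) {
    if (!is.null(flags[[fl]])) cfg[[num_flags[[fl]]]] <- as.numeric(flags[[fl]])
  }
  cfg <- validate_config(unclass(cfg))
  out <- flags$out
  data_dir <- if (!is.null(flags$data)) flags$data else out
  if (is.null(out) && is.null(data_dir)) stop("--out (or --data) is required")
  switch(cmd,
    simulate = cmd_simulate(cfg, out),
    detect = cmd_detect(cfg, data_dir, out_dir = if (is.null(out)) data_dir else out),
    activity = cmd_activity(cfg, data_dir, out_dir = if (is.null(out)) data_dir else out),
    align = cmd_align(cfg, data_dir, out_dir = if (is.null(out)) data_dir else out),
    models = cmd_models(cfg, data_dir, out_dir = if (is.null(out)) data_dir else out),
    all = cmd_all(cfg, out),
    stop("unknown subcommand: ", cmd)
  )
  invisible(0L)
}
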