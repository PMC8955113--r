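#' Run configuration for the monitoring pipelines
#'
#' One flat configuration drives both analyses (activity scoring and
#' fall-detection training/evaluation/detection). Every parameter
#' defaults to the package-wide default of its stage; a single top-level
#' seed fans out deterministically to all stages.
#'
#' @param ... named overrides of the defaults listed below.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    sensor_kind = "two_d",
    room_ids = "room1",
    # activity scoring
    delta_t = 1.5, min_active_pixels = 2, wma_window = 600,
    wma_decimation = NA, mask_update = TRUE,
    # skeleton / graph
    threshold = 28, binarize_mode = "fixed", min_component_px = 3,
    max_spur_px = 2, stride = 2, window_len = 24, hop = 8,
    # embedding / classifier
    k = 30, wl_depth = 3, epochs = 200, lr = 0.05, negative = 5,
    n_trees = 200, folds = 5,
    # dataset
    n_fall = 120, n_nonfall = 120, n_subjects = 10,
    seed = 0,
    out_dir = NULL
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as a flat key=value file
#'
#' @param cfg a [run_config()].
#' @param path file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns a `run_config` that round-trips the
#'   written values.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  keys <- names(cfg)
  vals <- vapply(keys, function(k) {
    v <- cfg[[k]]
    if (is.null(v)) "" else paste(as.character(v), collapse = ",")
  }, character(1))
  writeLines(paste0(keys, "=", vals), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  defaults <- run_config()
  cfg <- defaults
  for (m in kv) {
    key <- m[2]; val <- m[3]
    if (!key %in% names(defaults)) stop("unknown config key: ", key)
    proto <- defaults[[key]]
    cfg[[key]] <- if (is.null(proto) && val == "") NULL
      else if (is.null(proto)) val
      else if (val == "") proto
      else if (is.logical(proto)) as.logical(val)
      else if (is.numeric(proto)) as.numeric(val)
      else strsplit(val, ",", fixed = TRUE)[[1]]
  }
  class(cfg) <- "run_config"
  cfg
}

# machine-readable provenance: config hash, package version, seed
write_provenance <- function(cfg, path, extra = list()) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  write_run_config(cfg, tmp)
  rec <- c(list(
    config_md5 = unname(tools::md5sum(tmp)),
    package = "thermofall",
    version = as.character(utils::packageVersion("thermofall")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  ), extra)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run the activity-scoring pipeline
#'
#' Scores the given capture streams hour by hour and aggregates
#' per-month mean +/- standard deviation per hour of day. Invalid hours
#' (too few records) are excluded from the aggregation.
#'
#' @param streams named list of [thermal_stream()]s, one per room, or
#'   `NULL` to simulate `sim_hours` person-free hours per room from
#'   `sim_config` (occasional walking bouts are injected so the scores
#'   are non-trivial).
#' @param config a [run_config()].
#' @param dates Date (or vector, one per stream element) labeling the
#'   capture day.
#' @param sim_hours,sim_config simulation fallback parameters.
#' @param frame_rate nominal record rate for the validity rule.
#' @return List with `hourly` (the score series data frame), `monthly`
#'   (per-hour mean/sd data frame) and, when `config$out_dir` is set, the
#'   paths of the written CSVs and provenance record.
#' @export
run_activity_pipeline <- function(streams, config = run_config(),
                                  dates = as.Date("2020-08-01"),
                                  sim_hours = 1, sim_config = NULL,
                                  frame_rate = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(streams)) {
    if (is.null(sim_config)) {
      sim_config <- scene_config(seed = config$seed)
    }
    streams <- list()
    for (room in config$room_ids) {
      cfgr <- sim_config
      cfgr$seed <- sim_config$seed + length(streams)
      streams[[room]] <- simulate_background(
        cfgr, round(sim_hours * 3600 * cfgr$frame_rate_2d))
    }
  }
  if (is.null(names(streams)) || any(!nzchar(names(streams)))) {
    names(streams) <- paste0("room", seq_along(streams))
  }
  dates <- rep_len(as.Date(dates), length(streams))
  params <- activity_params(config$delta_t, config$min_active_pixels)
  dec <- if (is.na(config$wma_decimation)) NULL else config$wma_decimation
  hourly <- do.call(rbind, lapply(seq_along(streams), function(i) {
    score_hours(streams[[i]], date = dates[i], room = names(streams)[i],
                params = params, window_length = config$wma_window,
                decimation = dec, frame_rate = frame_rate,
                mask_update = config$mask_update)
  }))
  if (all(!hourly$valid)) {
    stop("no valid hours in any capture; nothing to score")
  }
  monthly <- monthly_mean_hour(hourly)
  out <- list(hourly = hourly, monthly = monthly)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    hp <- file.path(config$out_dir, "scores.csv")
    mp <- file.path(config$out_dir, "monthly.csv")
    pp <- file.path(config$out_dir, "provenance.json")
    utils::write.csv(hourly, hp, row.names = FALSE)
    utils::write.csv(monthly, mp, row.names = FALSE)
    write_provenance(config, pp, list(stage = "activity"))
    out$paths <- c(scores = hp, monthly = mp, provenance = pp)
  }
  out
}

#' Run the fall-detection pipeline end to end
#'
#' Generates (or accepts) the labeled window dataset, converts every
#' window to a spatiotemporal skeleton graph, fits the Graph2Vec-style
#' embedding and random forest, evaluates by stratified cross-validation,
#' and optionally runs a detection pass over a frame stream.
#'
#' @param config a [run_config()].
#' @param dataset optional prebuilt `fall_dataset`; by default one is
#'   generated from the config (`n_fall`/`n_nonfall`/`n_subjects`/seed).
#' @param detect_stream optional 2D [thermal_stream()] to scan for falls
#'   with the fitted model.
#' @return List with `report` (a `fall_eval`), `model` (a `fall_model`),
#'   `alerts` (data frame, when a detection stream was given) and any
#'   written paths.
#' @export
run_fall_pipeline <- function(config = run_config(), dataset = NULL,
                              detect_stream = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(dataset)) {
    dataset <- build_dataset(config$n_fall, config$n_nonfall,
                             config$n_subjects, seed = config$seed,
                             window_len = config$window_len)
  }
  wg <- window_graphs(dataset, threshold = config$threshold,
                      mode = config$binarize_mode,
                      min_component_px = config$min_component_px,
                      max_spur_px = config$max_spur_px,
                      stride = config$stride)
  emb <- fit_embedding(wg$graphs, k = config$k, depth = config$wl_depth,
                       epochs = config$epochs, lr = config$lr,
                       negative = config$negative, seed = config$seed)
  report <- cross_validate(wg$graphs, wg$labels, folds = config$folds,
                           n_trees = config$n_trees, seed = config$seed,
                           embedding = emb)
  model <- fall_model(wg$graphs, wg$labels, n_trees = config$n_trees,
                      seed = config$seed, embedding = emb)
  out <- list(report = report, model = model)
  if (!is.null(detect_stream)) {
    log_path <- if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      file.path(config$out_dir, "alerts.ndjson")
    }
    out$alerts <- detect_falls(model, detect_stream,
                               window_len = config$window_len,
                               hop = config$hop,
                               threshold = config$threshold,
                               stride = config$stride,
                               log_path = log_path)
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    pp <- file.path(config$out_dir, "provenance.json")
    write_provenance(config, pp, list(
      stage = "fall",
      precision = report$precision,
      sensitivity = report$sensitivity,
      specificity = report$specificity
    ))
    out$paths <- c(provenance = pp)
  }
  out
}
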