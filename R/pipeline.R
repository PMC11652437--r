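# End-to-end orchestration: generate -> process -> expose -> model, as a
# reproducible run with config, logging and derived seeds.

#' Default run configuration
#'
#' @param seed Run seed; every stochastic stage derives its own seed from it.
#' @param synthetic A [synthetic_config()] (its seed is overridden by
#'   `seed`).
#' @param gps [imputation_params()] values.
#' @param methods Activity-space methods to run: subset of `"kde"`,
#'   `"daily_path"`, `"residential_buffer"`.
#' @param bandwidth KDE bandwidth (250 primary; 100 in sensitivity runs).
#' @param daily_path_radius Metres (default 250).
#' @param residential_radii Metres (default c(800, 1600)).
#' @param residential_mode `"euclidean"` or `"network"`.
#' @param model_method `"ML"` or `"REML"`.
#' @param exposures,covariates Model terms (default: the package's full
#'   exposure and covariate rosters; small simulations may need a reduced
#'   covariate set to stay identifiable).
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1, synthetic = synthetic_config(seed = seed),
                       gps = imputation_params(),
                       methods = "kde", bandwidth = 250,
                       daily_path_radius = 250,
                       residential_radii = c(800, 1600),
                       residential_mode = "network",
                       model_method = "ML",
                       exposures = default_exposure_terms(),
                       covariates = default_covariates()) {
  synthetic$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), synthetic = synthetic, gps = gps,
                 methods = methods, bandwidth = bandwidth,
                 daily_path_radius = daily_path_radius,
                 residential_radii = residential_radii,
                 residential_mode = residential_mode,
                 model_method = model_method,
                 exposures = exposures, covariates = covariates),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with any subset of the [run_config()] fields
#'   (missing fields take their defaults).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  syn <- do.call(synthetic_config, c(
    raw$synthetic[setdiff(names(raw$synthetic), c("truth", "seed"))],
    list(truth = do.call(effect_truth, raw$synthetic$truth %||% list()),
         seed = raw$seed %||% 1)))
  run_config(seed = raw$seed %||% 1, synthetic = syn,
             gps = do.call(imputation_params, raw$gps %||% list()),
             methods = raw$methods %||% "kde",
             bandwidth = raw$bandwidth %||% 250,
             daily_path_radius = raw$daily_path_radius %||% 250,
             residential_radii = raw$residential_radii %||% c(800, 1600),
             residential_mode = raw$residential_mode %||% "network",
             model_method = raw$model_method %||% "ML",
             exposures = raw$exposures %||% default_exposure_terms(),
             covariates = raw$covariates %||% default_covariates())
}

#' @keywords internal
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(x))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

#' Load a written synthetic study directory
#'
#' Rebuilds the environment bundle from the gridded layers, the street
#' lattice from the config, and the roster, temperature and truth tables.
#'
#' @param dir Directory written by [generate_study()].
#' @return List: `env`, `roster`, `temperature`, `truth`, `config`.
#' @export
load_study <- function(dir) {
  cfgl <- yaml::read_yaml(file.path(dir, "config.yaml"))
  config <- do.call(synthetic_config, c(
    cfgl[setdiff(names(cfgl), "truth")],
    list(truth = do.call(effect_truth, cfgl$truth))))
  gre <- read_esri_ascii(file.path(dir, "env", "greenspace.asc"))
  grid <- gre$grid
  streets <- street_lattice(config$region_extent, config$block_size)
  roster <- utils::read.csv(file.path(dir, "roster.csv"),
                            stringsAsFactors = FALSE)
  env <- list(
    grid = grid, streets = streets,
    greenspace_layer = env_layer(grid, gre$values, "green_pct"),
    park_distance_layer = env_layer(
      grid, read_esri_ascii(file.path(dir, "env", "park_distance.asc"))$values,
      "park_distance_m"),
    parks_layer = env_layer(
      grid,
      {v <- read_esri_ascii(file.path(dir, "env", "parks.asc"))$values
       v[is.na(v)] <- 0; v},
      "park_indicator"),
    walkability_layer = env_layer(
      grid, read_esri_ascii(file.path(dir, "env", "walkability.asc"))$values,
      "walkability"),
    homes = data.frame(participant_id = roster$participant_id,
                       x = roster$home_x, y = roster$home_y))
  class(env) <- "environment_bundle"
  list(env = env, roster = roster,
       temperature = utils::read.csv(file.path(dir, "temperature.csv"),
                                     stringsAsFactors = FALSE),
       truth = utils::read.csv(file.path(dir, "truth.csv"),
                               stringsAsFactors = FALSE),
       config = config)
}

#' Process every GPS day in a study directory into exposure rows
#'
#' Reads each `gps/*.csv`, imputes gaps, applies the 6-h validity rule, and
#' derives the four exposure metrics by the requested method for valid
#' days (invalid days are retained as rows with `gps_valid = FALSE` and NA
#' metrics, so the exclusion ledger can count them).
#'
#' @param dir Study directory.
#' @param env Environment bundle (from [load_study()]).
#' @param gps_params [imputation_params()].
#' @param method,bandwidth,radius,residential_mode Passed to
#'   [derive_day_exposures()].
#' @return Data.frame of exposure rows.
#' @export
process_gps_days <- function(dir, env, gps_params = imputation_params(),
                             method = "kde", bandwidth = 250, radius = 250,
                             residential_mode = "euclidean") {
  files <- sort(list.files(file.path(dir, "gps"), pattern = "\\.csv$",
                           full.names = TRUE))
  day_type_of <- function(date) {
    ifelse(format(as.Date(date), "%u") %in% c("6", "7"),
           "weekend", "weekday")
  }
  rows <- lapply(files, function(f) {
    track <- read_gps_csv(f)
    attr(track, "day_type") <- day_type_of(attr(track, "date"))
    track <- impute_gaps(track, gps_params)
    v <- gps_day_valid(track)
    meta <- track_meta(track)
    base <- data.frame(participant_id = meta$participant_id,
                       wave = meta$wave, date = meta$date,
                       day_type = meta$day_type, method = method,
                       param_m = if (method == "kde") bandwidth else radius,
                       gps_valid = v$valid,
                       coverage_hours = v$coverage_hours,
                       stringsAsFactors = FALSE)
    if (!v$valid) {
      base$green_pct <- NA_real_; base$park_distance_m <- NA_real_
      base$parks_any <- NA_integer_; base$walkability <- NA_real_
      return(base)
    }
    ex <- derive_day_exposures(track, env, method = method,
                               bandwidth = bandwidth, radius = radius,
                               residential_mode = residential_mode)
    cbind(base, ex[, c("green_pct", "park_distance_m", "parks_any",
                       "walkability")])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Process every accelerometer day in a study directory
#'
#' @param dir Study directory.
#' @param params [freedson_params()].
#' @return Data.frame of day activity rows.
#' @export
process_accel_days <- function(dir, params = freedson_params()) {
  files <- sort(list.files(file.path(dir, "accel"), pattern = "\\.csv$",
                           full.names = TRUE))
  out <- do.call(rbind, lapply(files, function(f) {
    process_accel_day(read_accel_csv(f), params)
  }))
  rownames(out) <- NULL
  out
}

#' Run the full pipeline
#'
#' Generates (or loads) the synthetic study, processes GPS and
#' accelerometer days, derives exposures for each configured activity-space
#' method, assembles the panel, fits the null-ICC and main models, and
#' writes all tabular outputs plus a run manifest into a fresh run
#' directory (never overwritten).
#'
#' @param config A [run_config()].
#' @param out_dir Run directory to create.
#' @param data_dir Optional pre-existing study directory; by default the
#'   study is generated under `out_dir/data`.
#' @return Invisibly, a list with the panel(s) and model result(s) per
#'   method, and the manifest.
#' @export
run_pipeline <- function(config, out_dir, data_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0) {
    stop("run directory already exists and is not empty: ", out_dir)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    msg <- sprintf(...)
    message(msg)
    cat(msg, "\n", file = logf, append = TRUE, sep = "")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  if (is.null(data_dir)) {
    data_dir <- file.path(out_dir, "data")
    log_line("simulate: generating study (seed %d) under %s",
             config$seed, data_dir)
    stage("simulate", generate_study(config$synthetic, data_dir))
  }
  study <- stage("load", load_study(data_dir))
  log_line("activity: processing accelerometer days")
  activity <- stage("activity", process_accel_days(data_dir))
  utils::write.csv(activity, file.path(out_dir, "activity.csv"),
                   row.names = FALSE)
  results <- list()
  manifest_counts <- list()
  for (method in config$methods) {
    radii <- switch(method, kde = config$bandwidth,
                    daily_path = config$daily_path_radius,
                    residential_buffer = config$residential_radii)
    for (r in radii) {
      tag <- if (method == "kde") sprintf("kde%d", r)
             else if (method == "daily_path") sprintf("daily_path%d", r)
             else sprintf("residential%d", r)
      log_line("exposures: method %s", tag)
      expo <- stage(paste0("exposures:", tag), process_gps_days(
        data_dir, study$env, config$gps, method = method,
        bandwidth = r, radius = r,
        residential_mode = config$residential_mode))
      utils::write.csv(expo, file.path(out_dir,
                                       sprintf("exposures_%s.csv", tag)),
                       row.names = FALSE)
      panel <- stage(paste0("panel:", tag), {
        p <- assemble_panel(expo, activity, study$roster,
                            study$temperature, quiet = TRUE)
        p$log_mvpa <- transform_outcome(p$mvpa_minutes)
        person_mean_center(p)
      })
      excl <- attr(panel, "exclusions")
      manifest_counts[[tag]] <- as.list(excl)
      log_line("panel %s: %d accel days -> %d retained", tag,
               excl["accel_days"], excl["final"])
      utils::write.csv(panel, file.path(out_dir,
                                        sprintf("panel_%s.csv", tag)),
                       row.names = FALSE)
      icc <- stage(paste0("icc:", tag), fit_null_icc(panel))
      fit <- stage(paste0("model:", tag),
                   fit_main_model(panel, exposures = config$exposures,
                                  covariates = config$covariates,
                                  method = config$model_method))
      utils::write.csv(fit$tidy, file.path(out_dir,
                                           sprintf("model_%s.csv", tag)),
                       row.names = FALSE)
      log_line("model %s: ICC %.3f, WS parks exp(b) %.3f", tag, icc$icc,
               fit$tidy$estimate_exp[fit$tidy$term == "parks_any_ws"])
      results[[tag]] <- list(panel = panel, icc = icc, model = fit)
    }
  }
  cfg_yaml <- yaml::as.yaml(rapply(unclass(config), unclass, how = "replace"))
  manifest <- list(seed = config$seed, config_hash = fnv1a_hash(cfg_yaml),
                   methods = names(results), exclusions = manifest_counts,
                   package_version = as.character(
                     utils::packageVersion("dayspace")))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  writeLines(cfg_yaml, file.path(out_dir, "config_used.yaml"))
  invisible(list(results = results, manifest = manifest, dir = out_dir))
}
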