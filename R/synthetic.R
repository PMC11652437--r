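# Synthetic study generator: environment layers, participant roster, GPS
# days, accelerometer days, with known ground-truth effect sizes so every
# downstream stage can be tested without restricted cohort data.

#' Ground-truth effect sizes for the synthetic outcome model
#'
#' Daily MVPA minutes are generated on the log scale as
#' `mean_log_mvpa + person effect + log(within_park_effect) * park day +
#' log(within_walkability_effect) * walkability deviation + day noise`,
#' with person effects N(0, between_sd^2) and day noise N(0, within_sd^2).
#' The default variance split (0.55^2 between, 0.66^2 within) puts 41% of
#' log-outcome variance between persons.
#'
#' @param within_park_effect Multiplicative effect on MVPA minutes of any
#'   park/open-space exposure that day (default 1.25).
#' @param within_walkability_effect Multiplicative effect per unit of
#'   day-level walkability deviation (default 1, i.e. null).
#' @param between_sd,within_sd SDs of person-level and day-level log-MVPA
#'   noise (defaults 0.55, 0.66).
#' @param mean_log_mvpa Baseline log MVPA minutes (default 3.0).
#' @return An `effect_truth` list.
#' @export
effect_truth <- function(within_park_effect = 1.25,
                         within_walkability_effect = 1,
                         between_sd = 0.55, within_sd = 0.66,
                         mean_log_mvpa = 3.0) {
  if (within_park_effect <= 0 || within_walkability_effect <= 0) {
    stop("multiplicative effects must be positive")
  }
  if (between_sd <= 0 || within_sd <= 0) stop("SDs must be positive")
  structure(list(within_park_effect = within_park_effect,
                 within_walkability_effect = within_walkability_effect,
                 between_sd = between_sd, within_sd = within_sd,
                 mean_log_mvpa = mean_log_mvpa),
            class = "effect_truth")
}

#' Synthetic study configuration
#'
#' Encodes the study-design constants (55 participants, three waves of four
#' days each, two weekdays plus two weekend days) and the movement,
#' environment and degradation parameters of the generator.
#'
#' @param n_participants Participants (default 55; at least 2).
#' @param waves Wave labels (first trimester, third trimester, 4-6 months
#'   postpartum).
#' @param days_per_wave Observation days per wave (default 4; at least 2;
#'   split between weekdays and weekend days).
#' @param region_extent Side of the square study region, metres (default
#'   10000; a positive multiple of `cell_size` and `block_size`).
#' @param cell_size Analysis grid cell, metres (default 50).
#' @param block_size Street lattice block, metres (default 200).
#' @param bandwidth KDE bandwidth used for ground-truth exposure, metres.
#' @param n_parks Number of rectangular parks, 1-4 (default 2).
#' @param tract_size Walkability tract patch size, metres (default 1000).
#' @param park_visit_prob Probability a day's itinerary includes a park
#'   visit (default 0.6).
#' @param waking_start_hour,waking_hours Waking window (default 07:00, 14 h).
#' @param walk_speed Walking speed, m/s (default 1.2).
#' @param jitter_sd GPS position noise SD, metres (default 10).
#' @param gps_dropout_prob,gps_severe_prob Fractions of days given moderate
#'   (0.5-4 h) and severe (>8 h, below the 6-h validity floor) contiguous
#'   GPS deletions.
#' @param accel_nonwear_prob Fraction of days given a >60-min zero block.
#' @param accel_lowwear_prob Fraction of days degraded below 10 h of wear.
#' @param seed Integer seed; all generation is a pure function of
#'   (config, seed).
#' @param truth An [effect_truth()] object.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_participants = 55,
                             waves = c("T1", "T3", "PP"),
                             days_per_wave = 4,
                             region_extent = 10000,
                             cell_size = 50, block_size = 200,
                             bandwidth = 250,
                             n_parks = 2, tract_size = 1000,
                             park_visit_prob = 0.6,
                             waking_start_hour = 7, waking_hours = 14,
                             walk_speed = 1.2, jitter_sd = 10,
                             gps_dropout_prob = 0.2, gps_severe_prob = 0.12,
                             accel_nonwear_prob = 0.15,
                             accel_lowwear_prob = 0.25,
                             seed = 1, truth = effect_truth()) {
  if (n_participants < 2) stop("n_participants must be at least 2")
  if (days_per_wave < 2) stop("days_per_wave must be at least 2")
  if (region_extent <= 0 || region_extent %% cell_size != 0) {
    stop("region_extent must be a positive multiple of cell_size")
  }
  if (region_extent %% block_size != 0) {
    stop("region_extent must be a multiple of block_size")
  }
  structure(list(
    n_participants = as.integer(n_participants), waves = waves,
    days_per_wave = as.integer(days_per_wave),
    region_extent = region_extent, cell_size = cell_size,
    block_size = block_size, bandwidth = bandwidth,
    n_parks = as.integer(n_parks), tract_size = tract_size,
    park_visit_prob = park_visit_prob,
    waking_start_hour = waking_start_hour, waking_hours = waking_hours,
    walk_speed = walk_speed, jitter_sd = jitter_sd,
    gps_dropout_prob = gps_dropout_prob, gps_severe_prob = gps_severe_prob,
    accel_nonwear_prob = accel_nonwear_prob,
    accel_lowwear_prob = accel_lowwear_prob,
    seed = as.integer(seed), truth = truth), class = "synthetic_config")
}

# Observation dates per wave: weekdays from the wave's base Monday, weekend
# days from the same week's Saturday, alternating to fill days_per_wave.
#' @keywords internal
wave_dates <- function(config) {
  base <- c(T1 = "2017-03-06", T3 = "2017-09-04", PP = "2018-02-05")
  out <- list()
  for (w in config$waves) {
    monday <- as.Date(base[[w]] %||% "2017-06-05")
    n_wd <- ceiling(config$days_per_wave / 2)
    n_we <- config$days_per_wave - n_wd
    wd <- monday + (seq_len(n_wd) - 1) %% 5 + 7 * ((seq_len(n_wd) - 1) %/% 5)
    we <- monday + 5 + c(0, 1, 7, 8, 14, 15)[seq_len(n_we)]
    d <- sort(c(wd, we))
    out[[w]] <- data.frame(
      date = format(d, "%Y-%m-%d"),
      day_type = ifelse(format(d, "%u") %in% c("6", "7"),
                        "weekend", "weekday"),
      stringsAsFactors = FALSE)
  }
  out
}

#' Generate the synthetic environment
#'
#' Builds a Manhattan street lattice with per-segment greenspace
#' percentages, 1-4 rectangular parks with entrance points on their
#' boundaries, a mosaic of tract-like walkability patches, and the four
#' gridded layers. Layers are produced by the same gridding operations the
#' exposure pipeline uses, so generator and pipeline share one code path.
#'
#' @param config A [synthetic_config()].
#' @return An `environment_bundle`: `grid`, `streets`, `parks`,
#'   `entrances`, `tracts`, the four `env_layer`s, and (once a roster is
#'   attached) `homes`.
#' @export
generate_environment <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$n_parks < 1) {
    stop("at least one park is required; park distance is undefined without parks")
  }
  if (config$n_parks > 4) stop("n_parks must be between 1 and 4")
  min_park <- 4 * config$cell_size
  if (config$region_extent < 2 * min_park) {
    stop("region too small to contain one park at the requested cell size")
  }
  set.seed(derive_seed(config$seed, "environment"))
  L <- config$region_extent
  streets <- street_lattice(L, config$block_size)
  streets$segments$green_pct <- pmin(100, pmax(0,
    stats::rnorm(nrow(streets$segments), 23.3, 8.3)))
  # parks: rectangles snapped to the cell lattice, kept inside the region
  sizes <- config$cell_size * sample(4:12, config$n_parks, replace = TRUE)
  parks <- data.frame(xmin = numeric(0), xmax = numeric(0),
                      ymin = numeric(0), ymax = numeric(0))
  for (i in seq_len(config$n_parks)) {
    wpx <- sizes[i]
    hpx <- config$cell_size * sample(4:12, 1)
    x0 <- config$cell_size *
      sample.int((L - wpx) / config$cell_size - 1, 1)
    y0 <- config$cell_size *
      sample.int((L - hpx) / config$cell_size - 1, 1)
    parks <- rbind(parks, data.frame(xmin = x0, xmax = x0 + wpx,
                                     ymin = y0, ymax = y0 + hpx))
  }
  parks$name <- sprintf("park_%d", seq_len(nrow(parks)))
  # one entrance at the midpoint of the south edge, a second on the east
  # edge for larger parks
  ent <- data.frame(x = (parks$xmin + parks$xmax) / 2, y = parks$ymin,
                    park = parks$name)
  big <- (parks$xmax - parks$xmin) >= 6 * config$cell_size
  if (any(big)) {
    ent <- rbind(ent, data.frame(x = parks$xmax[big],
                                 y = (parks$ymin[big] + parks$ymax[big]) / 2,
                                 park = parks$name[big]))
  }
  # walkability tract mosaic
  k <- max(1L, as.integer(L / config$tract_size))
  tx <- seq(0, L, length.out = k + 1)
  tracts <- expand.grid(i = seq_len(k), j = seq_len(k))
  tracts <- data.frame(
    xmin = tx[tracts$i], xmax = tx[tracts$i + 1],
    ymin = tx[tracts$j], ymax = tx[tracts$j + 1],
    score = pmin(20, pmax(1, round(stats::rnorm(nrow(tracts), 15, 2)))))
  grid <- make_grid_spec(c(0, L, 0, L), config$cell_size,
                         pad = config$bandwidth)
  bundle <- list(
    grid = grid, streets = streets, parks = parks, entrances = ent,
    tracts = tracts,
    greenspace_layer = rasterize_street_greenspace(streets, grid),
    park_distance_layer = park_distance_layer(ent, grid, "euclidean"),
    parks_layer = rasterize_parks(parks, grid),
    walkability_layer = rasterize_walkability(tracts, grid),
    homes = NULL)
  class(bundle) <- "environment_bundle"
  bundle
}

#' Generate the participant roster
#'
#' Person-level covariates drawn to match the cohort's descriptive
#' statistics: age N(29.0, 6.1) truncated at 18, education (34.55% some
#' college or more), parity (29.09% first-born), pre-pregnancy BMI category
#' (27.3/34.5/38.2% normal/overweight/obese), employment (36.17%),
#' deprivation index 1-10 around 6.34 (1.78), cohesion/safety score 1-5
#' around 3.02 (0.69). Homes are snapped to interior street-lattice nodes.
#'
#' @param config A [synthetic_config()].
#' @return Data.frame, one row per participant.
#' @export
generate_participant_roster <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(derive_seed(config$seed, "roster"))
  n <- config$n_participants
  age <- stats::rnorm(n, 29.0, 6.1)
  while (any(age < 18)) {
    i <- age < 18
    age[i] <- stats::rnorm(sum(i), 29.0, 6.1)
  }
  k <- as.integer(config$region_extent / config$block_size)
  hx <- config$block_size * sample(1:(k - 1), n, replace = TRUE)
  hy <- config$block_size * sample(1:(k - 1), n, replace = TRUE)
  data.frame(
    participant_id = sprintf("P%03d", seq_len(n)),
    age = age,
    education = sample(c("some_college_plus", "high_school_or_less"), n,
                       replace = TRUE, prob = c(0.3455, 0.6545)),
    parity = sample(c("first_born", "second_or_greater"), n,
                    replace = TRUE, prob = c(0.2909, 0.7091)),
    bmi_category = sample(c("normal", "overweight", "obese"), n,
                          replace = TRUE,
                          prob = c(0.2727, 0.3450, 0.3820) / 0.9997),
    employed = stats::rbinom(n, 1, 0.3617),
    deprivation = pmin(10, pmax(1, round(stats::rnorm(n, 6.34, 1.78)))),
    cohesion_safety = pmin(5, pmax(1, stats::rnorm(n, 3.02, 0.69))),
    home_x = hx, home_y = hy,
    stringsAsFactors = FALSE)
}

# Manhattan L-path waypoints between two lattice-ish points (horizontal
# then vertical leg).
#' @keywords internal
l_path <- function(from, to) {
  if (from[1] == to[1] || from[2] == to[2]) {
    rbind(from, to)
  } else {
    rbind(from, c(to[1], from[2]), to)
  }
}

# Positions along a timed itinerary at the requested epoch times.
# waypoints: matrix of (t, x, y) rows with non-decreasing t.
#' @keywords internal
itinerary_positions <- function(waypoints, t_epochs) {
  wt <- waypoints[, 1]
  keep <- c(TRUE, diff(wt) > 0)
  wx <- waypoints[keep, 2]; wy <- waypoints[keep, 3]; wt <- wt[keep]
  x <- stats::approx(wt, wx, xout = t_epochs, rule = 2)$y
  y <- stats::approx(wt, wy, xout = t_epochs, rule = 2)$y
  cbind(x, y)
}

#' Generate one synthetic GPS day
#'
#' A two-anchor movement model: a home dwell, a walk along streets to a
#' secondary anchor, an optional park visit, and a return, all at a fixed
#' walking speed, sampled at 10-s epochs over the waking window with
#' Gaussian position jitter. Contiguous blocks are then deleted to emulate
#' missingness; the pre-deletion track is kept in the `"full_track"`
#' attribute for ground-truth exposure.
#'
#' @param participant One roster row (needs `home_x`, `home_y`,
#'   `participant_id`).
#' @param wave Wave label.
#' @param date,day_type Observation date and type.
#' @param env An `environment_bundle`.
#' @param config A [synthetic_config()].
#' @param seed Integer seed (required).
#' @return A `gps_track` (post-deletion) with attributes `full_track`,
#'   `window` (c(start, end) seconds) and `itinerary` (list with
#'   `park_visit`).
#' @export
generate_gps_day <- function(participant, wave, date, day_type, env, config,
                             seed) {
  require_seed(seed)
  set.seed(seed)
  L <- config$region_extent
  home <- c(participant$home_x, participant$home_y)
  if (any(home < 0) || any(home > L)) stop("participant home outside region")
  start <- as.integer(config$waking_start_hour * 3600)
  n_ep <- as.integer(config$waking_hours * 360)
  t_ep <- start + 10L * (seq_len(n_ep) - 1L)
  blk <- config$block_size
  k <- as.integer(L / blk)
  # secondary anchor: interior lattice node 2-10 blocks away (manhattan)
  repeat {
    sec <- blk * c(sample(1:(k - 1), 1), sample(1:(k - 1), 1))
    man <- sum(abs(sec - home))
    if (man >= 2 * blk && man <= 10 * blk) break
  }
  park_visit <- stats::runif(1) < config$park_visit_prob
  v <- config$walk_speed
  wp <- matrix(c(start, home), 1)
  t_cur <- start + round(stats::runif(1, 3600, 3 * 3600))
  add_leg <- function(wp, t_cur, path) {
    for (i in 2:nrow(path)) {
      d <- sqrt(sum((path[i, ] - path[i - 1, ])^2))
      wp <- rbind(wp, c(t_cur, path[i - 1, ]))
      t_cur <- t_cur + d / v
      wp <- rbind(wp, c(t_cur, path[i, ]))
    }
    list(wp = wp, t = t_cur)
  }
  leg <- add_leg(wp, t_cur, l_path(home, sec))
  wp <- leg$wp; t_cur <- leg$t + round(stats::runif(1, 3600, 3 * 3600))
  if (park_visit) {
    p <- env$parks[sample.int(nrow(env$parks), 1), ]
    target <- c(stats::runif(1, p$xmin + 5, p$xmax - 5),
                stats::runif(1, p$ymin + 5, p$ymax - 5))
    gate <- blk * round(target / blk)  # street node near the park
    leg <- add_leg(wp, t_cur, l_path(sec, gate))
    wp <- leg$wp; t_cur <- leg$t
    leg <- add_leg(wp, t_cur, rbind(gate, target))
    wp <- leg$wp; t_cur <- leg$t + round(stats::runif(1, 1800, 5400))
    leg <- add_leg(wp, t_cur, rbind(target, gate))
    wp <- leg$wp; t_cur <- leg$t
    leg <- add_leg(wp, t_cur, l_path(gate, home))
    wp <- leg$wp
  } else {
    leg <- add_leg(wp, t_cur, l_path(sec, home))
    wp <- leg$wp
  }
  pos <- itinerary_positions(wp, t_ep)
  x <- pos[, 1] + stats::rnorm(n_ep, 0, config$jitter_sd)
  y <- pos[, 2] + stats::rnorm(n_ep, 0, config$jitter_sd)
  meta <- list(participant_id = participant$participant_id, wave = wave,
               date = date, day_type = day_type)
  full <- gps_track(t_ep, x, y, participant_id = meta$participant_id,
                    wave = wave, date = date, day_type = day_type)
  keep <- rep(TRUE, n_ep)
  u <- stats::runif(1)
  if (u < config$gps_severe_prob) {
    len <- as.integer(round(stats::runif(1, 8.5, 12) * 360))
    len <- min(len, n_ep - 12L)
    s0 <- sample.int(n_ep - len, 1)
    keep[s0:(s0 + len - 1L)] <- FALSE
  } else if (u < config$gps_severe_prob + config$gps_dropout_prob) {
    nblk <- sample(1:3, 1)
    total <- as.integer(round(stats::runif(1, 0.5, 4) * 360))
    per <- pmax(6L, as.integer(round(total / nblk)))
    for (b in seq_len(nblk)) {
      s0 <- sample.int(n_ep - per, 1)
      keep[s0:(s0 + per - 1L)] <- FALSE
    }
  }
  obs <- gps_track(t_ep[keep], x[keep], y[keep],
                   participant_id = meta$participant_id, wave = wave,
                   date = date, day_type = day_type)
  attr(obs, "full_track") <- full
  attr(obs, "window") <- c(start, start + n_ep * 10L)
  attr(obs, "itinerary") <- list(park_visit = park_visit, secondary = sec)
  obs
}

#' Generate one synthetic accelerometer day
#'
#' The day's ground-truth exposure is computed from the GPS day's
#' pre-deletion track with the pipeline's own exposure operations; the
#' outcome model of [effect_truth()] then fixes a target MVPA duration,
#' realized exactly as `round(target * 6)` above-threshold 10-s epochs laid
#' out in bouts over a low-count baseline. A configurable fraction of days
#' receives a >60-min zero block (non-wear) or is degraded below 10 h of
#' wear; those days are flagged `degraded` in the truth attribute.
#'
#' @param gps_day A track from [generate_gps_day()].
#' @param truth An [effect_truth()].
#' @param env The `environment_bundle` (for ground-truth exposure).
#' @param config A [synthetic_config()].
#' @param person_effect This participant's person-level log-MVPA effect.
#' @param seed Integer seed (required).
#' @return An `accel_series` with a `truth` attribute (list: `park`,
#'   `walk_dev`, `target_log`, `mvpa_minutes`, `degraded`).
#' @export
generate_accel_day <- function(gps_day, truth, env, config,
                               person_effect = 0, seed) {
  require_seed(seed)
  window <- attr(gps_day, "window")
  if (is.null(window)) stop("gps_day carries no waking window")
  full <- attr(gps_day, "full_track") %||% gps_day
  if (nrow(full) == 0 || full$t[1] < window[1] ||
      full$t[nrow(full)] >= window[2]) {
    stop("accelerometer window does not match the GPS day")
  }
  expo <- derive_day_exposures(full, env, method = "kde",
                               bandwidth = config$bandwidth)
  walk_ref <- mean(env$walkability_layer$values, na.rm = TRUE)
  walk_dev <- expo$walkability - walk_ref
  set.seed(seed)
  eta <- truth$mean_log_mvpa + person_effect +
    log(truth$within_park_effect) * expo$parks_any +
    log(truth$within_walkability_effect) * walk_dev +
    stats::rnorm(1, 0, truth$within_sd)
  target <- exp(eta)
  n_ep <- as.integer((window[2] - window[1]) / 10)
  t_ep <- window[1] + 10L * (seq_len(n_ep) - 1L)
  counts <- pmin(500L, stats::rpois(n_ep, 20))
  n_mvpa <- min(round(target * 6), as.integer(0.5 * n_ep))
  if (n_mvpa > 0) {
    n_bouts <- max(1L, as.integer(ceiling(n_mvpa / 120)))
    per <- diff(round(seq(0, n_mvpa, length.out = n_bouts + 1)))
    chunk <- n_ep %/% n_bouts
    for (b in seq_len(n_bouts)) {
      if (per[b] == 0) next
      lo <- (b - 1L) * chunk + 1L
      s0 <- lo + sample.int(max(1L, chunk - per[b]), 1) - 1L
      counts[s0:(s0 + per[b] - 1L)] <- 600L +
        sample.int(800L, per[b], replace = TRUE)
    }
  }
  degraded <- FALSE
  u <- stats::runif(1)
  if (u < config$accel_lowwear_prob) {
    wear_target <- stats::runif(1, 6, 9.5)
    nz <- n_ep - as.integer(round(wear_target * 360))
    if (nz > 360) {
      counts[seq_len(nz)] <- 0L
      degraded <- TRUE
    }
  } else if (u < config$accel_lowwear_prob + config$accel_nonwear_prob) {
    len <- as.integer(round(stats::runif(1, 61, 150) * 6))
    s0 <- sample.int(n_ep - len, 1)
    counts[s0:(s0 + len - 1L)] <- 0L
    degraded <- TRUE
  }
  series <- accel_series(t_ep, counts,
                         participant_id = attr(gps_day, "participant_id"),
                         wave = attr(gps_day, "wave"),
                         date = attr(gps_day, "date"))
  attr(series, "truth") <- list(
    park = expo$parks_any, walk_dev = walk_dev, target_log = eta,
    mvpa_minutes = n_mvpa / 6, degraded = degraded)
  series
}

#' Generate and write a full synthetic study
#'
#' Runs the environment, roster, GPS and accelerometer generators for every
#' person-wave-day, draws a shared daily temperature series N(19.92, 4.40),
#' and writes the study tree: `env/` (Esri ASCII layers plus GeoJSON
#' vectors), `gps/<pid>_<wave>_<date>.csv`, `accel/<pid>_<wave>_<date>.csv`,
#' `roster.csv`, `temperature.csv`, `truth.csv` and `config.yaml`. Output is
#' a pure function of the config (same seed, byte-identical tree).
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created; must be writable).
#' @return Invisibly, a list with `dir`, `env`, `roster`, `truth` and
#'   `temperature`.
#' @export
generate_study <- function(config, out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("output directory is not writable")
  for (d in c("env", "gps", "accel")) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  }
  env <- generate_environment(config)
  roster <- generate_participant_roster(config)
  env$homes <- data.frame(participant_id = roster$participant_id,
                          x = roster$home_x, y = roster$home_y)
  set.seed(derive_seed(config$seed, "person_effects"))
  person_effect <- stats::rnorm(config$n_participants, 0,
                                config$truth$between_sd)
  dates <- wave_dates(config)
  all_dates <- unique(unlist(lapply(dates, `[[`, "date")))
  set.seed(derive_seed(config$seed, "temperature"))
  temperature <- data.frame(
    date = sort(all_dates),
    temp_c = stats::rnorm(length(all_dates), 19.92, 4.40))
  # environment files
  g <- env$grid
  write_esri_ascii(g, env$greenspace_layer$values,
                   file.path(out_dir, "env", "greenspace.asc"))
  write_esri_ascii(g, env$park_distance_layer$values,
                   file.path(out_dir, "env", "park_distance.asc"))
  write_esri_ascii(g, env$parks_layer$values,
                   file.path(out_dir, "env", "parks.asc"))
  write_esri_ascii(g, env$walkability_layer$values,
                   file.path(out_dir, "env", "walkability.asc"))
  write_geojson_rectangles(env$parks, file.path(out_dir, "env",
                                                "parks.geojson"))
  write_geojson_points(env$entrances, file.path(out_dir, "env",
                                                "entrances.geojson"))
  write_geojson_points(env$homes, file.path(out_dir, "env", "homes.geojson"))
  write_geojson_lines(env$streets$segments,
                      file.path(out_dir, "env", "streets.geojson"))
  utils::write.csv(roster, file.path(out_dir, "roster.csv"),
                   row.names = FALSE)
  utils::write.csv(temperature, file.path(out_dir, "temperature.csv"),
                   row.names = FALSE)
  truth_rows <- list()
  for (i in seq_len(config$n_participants)) {
    p <- roster[i, ]
    for (w in config$waves) {
      for (j in seq_len(nrow(dates[[w]]))) {
        dt <- dates[[w]]$date[j]
        day_type <- dates[[w]]$day_type[j]
        tag <- paste(p$participant_id, w, dt, sep = "_")
        gps <- generate_gps_day(p, w, dt, day_type, env, config,
                                seed = derive_seed(config$seed,
                                                   paste0("gps:", tag)))
        acc <- generate_accel_day(gps, config$truth, env, config,
                                  person_effect = person_effect[i],
                                  seed = derive_seed(config$seed,
                                                     paste0("accel:", tag)))
        write_track_csv(gps, file.path(out_dir, "gps",
                                       paste0(tag, ".csv")))
        write_accel_csv(acc, file.path(out_dir, "accel",
                                       paste0(tag, ".csv")))
        tr <- attr(acc, "truth")
        truth_rows[[tag]] <- data.frame(
          participant_id = p$participant_id, wave = w, date = dt,
          day_type = day_type, park_exposed = tr$park,
          walk_dev = tr$walk_dev, person_effect = person_effect[i],
          target_log = tr$target_log, mvpa_minutes = tr$mvpa_minutes,
          gps_epochs = nrow(gps), accel_degraded = tr$degraded,
          stringsAsFactors = FALSE)
      }
    }
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  cfg <- config
  cfg$truth <- unclass(cfg$truth)
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))
  invisible(list(dir = out_dir, env = env, roster = roster, truth = truth,
                 temperature = temperature))
}

#' Write a GPS track as a day CSV
#'
#' @param track A `gps_track`.
#' @param path Output path.
#' @export
write_track_csv <- function(track, path) {
  date <- attr(track, "date") %||% "2017-01-01"
  df <- data.frame(timestamp_iso = format_iso(date, track$t),
                   x_m = sprintf("%.3f", track$x),
                   y_m = sprintf("%.3f", track$y))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an accelerometer series as a day CSV
#'
#' @param series An `accel_series`.
#' @param path Output path.
#' @export
write_accel_csv <- function(series, path) {
  date <- attr(series, "date") %||% "2017-01-01"
  df <- data.frame(timestamp_iso = format_iso(date, series$t),
                   counts = series$counts)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulate an analysis-ready panel directly from the truth model
#'
#' The panel-level arm of the generator: exposures and outcomes are drawn
#' straight from the [effect_truth()] model (person effects, day-level park
#' exposure, walkability deviations, log-normal day noise, epoch-rounded
#' MVPA minutes) with covariates from [generate_participant_roster()],
#' skipping the GPS/KDE geometry. Used for parameter-recovery and
#' null-calibration experiments where hundreds of replicates are fitted.
#'
#' @param n_participants Persons (default 55).
#' @param days_per_person Valid days each (default 8).
#' @param truth An [effect_truth()].
#' @param park_prob Probability of day-level park exposure (default 0.6).
#' @param seed Integer seed (required).
#' @return A data.frame ready for [person_mean_center()] and model fitting:
#'   identifiers, the four exposure metrics, covariates and `mvpa_minutes`.
#' @export
simulate_analysis_panel <- function(n_participants = 55,
                                    days_per_person = 8,
                                    truth = effect_truth(),
                                    park_prob = 0.6, seed) {
  require_seed(seed)
  cfg <- synthetic_config(n_participants = n_participants, seed = seed)
  roster <- generate_participant_roster(cfg)
  set.seed(derive_seed(seed, "panel"))
  n <- n_participants * days_per_person
  pid <- rep(roster$participant_id, each = days_per_person)
  i <- rep(seq_len(n_participants), each = days_per_person)
  person_effect <- stats::rnorm(n_participants, 0, truth$between_sd)
  green_i <- pmin(100, pmax(0, stats::rnorm(n_participants, 23.3, 7)))
  dist_i <- pmax(50, stats::rnorm(n_participants, 790.8, 350))
  walk_i <- pmin(19, pmax(2, stats::rnorm(n_participants, 15.0, 1.5)))
  green <- pmin(100, pmax(0, green_i[i] + stats::rnorm(n, 0, 3.5)))
  dist <- pmax(0, dist_i[i] + stats::rnorm(n, 0, 150))
  walk <- pmin(20, pmax(1, walk_i[i] + stats::rnorm(n, 0, 0.8)))
  park <- stats::rbinom(n, 1, park_prob)
  eta <- truth$mean_log_mvpa + person_effect[i] +
    log(truth$within_park_effect) * park +
    log(truth$within_walkability_effect) * (walk - 15) +
    stats::rnorm(n, 0, truth$within_sd)
  mvpa <- round(exp(eta) * 6) / 6  # epoch-rounded minutes
  out <- data.frame(
    participant_id = pid,
    wave = sample(c("T1", "T3", "PP"), n, replace = TRUE,
                  prob = c(0.38, 0.303, 0.317)),
    date = sprintf("d%02d", rep(seq_len(days_per_person), n_participants)),
    day_type = ifelse(stats::rbinom(n, 1, 0.4543) == 1,
                      "weekend", "weekday"),
    green_pct = green, park_distance_m = dist,
    park_distance_100m = dist / 100, parks_any = park,
    walkability = walk,
    age = roster$age[i], education = roster$education[i],
    parity = roster$parity[i], bmi_category = roster$bmi_category[i],
    employed = roster$employed[i], deprivation = roster$deprivation[i],
    cohesion_safety = roster$cohesion_safety[i],
    temp_c = stats::rnorm(n, 19.92, 4.40),
    wear_hours = pmin(16, pmax(10, stats::rnorm(n, 13.79, 2.63))),
    mvpa_minutes = mvpa,
    stringsAsFactors = FALSE)
  out$weekend <- as.integer(out$day_type == "weekend")
  person_mean_center(out)
}
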