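#' GPS track container
#'
#' One participant-day of planar positions on the 10-s epoch lattice.
#'
#' @param t Integer seconds since local day start; must be strictly
#'   increasing multiples of 10.
#' @param x,y Planar coordinates, metres.
#' @param imputed Logical flag per epoch.
#' @param participant_id,wave,date,day_type Identifying metadata; `wave` one
#'   of `"T1"`, `"T3"`, `"PP"`, `day_type` `"weekday"` or `"weekend"`.
#' @return A `gps_track` (data.frame with attributes).
#' @export
gps_track <- function(t, x, y, imputed = rep(FALSE, length(t)),
                      participant_id = NA_character_, wave = NA_character_,
                      date = NA_character_, day_type = NA_character_) {
  stopifnot(length(t) == length(x), length(x) == length(y),
            length(imputed) == length(t))
  if (length(t)) {
    if (any(!is.finite(x)) || any(!is.finite(y))) {
      stop("coordinates must be finite")
    }
    if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
    if (any(t %% 10 != 0)) stop("timestamps must lie on the 10-s lattice")
  }
  out <- data.frame(t = as.integer(t), x = as.numeric(x), y = as.numeric(y),
                    imputed = as.logical(imputed))
  structure(out, class = c("gps_track", "data.frame"),
            participant_id = participant_id, wave = wave, date = date,
            day_type = day_type)
}

#' @keywords internal
track_meta <- function(track) {
  list(participant_id = attr(track, "participant_id"),
       wave = attr(track, "wave"), date = attr(track, "date"),
       day_type = attr(track, "day_type"))
}

#' Read a one-day GPS epoch stream from CSV
#'
#' Expects columns `timestamp_iso,x_m,y_m`. Rows are sorted by time;
#' duplicate timestamps are collapsed to the first occurrence with a warning;
#' timestamps off the 10-s lattice are snapped down with a warning. An empty
#' file (header only) yields an empty track.
#'
#' @param path CSV file path.
#' @param participant_id,wave,date,day_type Metadata attached to the track
#'   (defaults parsed from a `<pid>_<wave>_<day>.csv` filename where possible).
#' @return A `gps_track`.
#' @export
read_gps_csv <- function(path, participant_id = NULL, wave = NULL,
                         date = NULL, day_type = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta <- parse_day_filename(path)
  participant_id <- participant_id %||% meta$pid
  wave <- wave %||% meta$wave
  date <- date %||% meta$day
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!all(c("timestamp_iso", "x_m", "y_m") %in% names(raw))) {
    stop("expected header timestamp_iso,x_m,y_m in ", path)
  }
  if (nrow(raw) == 0) {
    return(gps_track(integer(), numeric(), numeric(),
                     participant_id = participant_id, wave = wave,
                     date = date, day_type = day_type))
  }
  secs <- parse_iso_seconds(raw$timestamp_iso)
  xs <- suppressWarnings(as.numeric(raw$x_m))
  ys <- suppressWarnings(as.numeric(raw$y_m))
  bad <- which(is.na(secs) | is.na(xs) | is.na(ys))
  if (length(bad)) {
    stop(sprintf("unparseable GPS row at line %d of %s", bad[1] + 1L, path))
  }
  off <- secs %% 10 != 0
  if (any(off)) {
    warning(sprintf("%d timestamps off the 10-s lattice snapped down in %s",
                    sum(off), basename(path)))
    secs <- secs - secs %% 10
  }
  o <- order(secs)
  secs <- secs[o]; xs <- xs[o]; ys <- ys[o]
  dup <- duplicated(secs)
  if (any(dup)) {
    warning(sprintf("%d duplicate timestamps collapsed in %s",
                    sum(dup), basename(path)))
    xs <- xs[!dup]; ys <- ys[!dup]; secs <- secs[!dup]
  }
  gps_track(secs, xs, ys, participant_id = participant_id, wave = wave,
            date = date, day_type = day_type)
}

#' Gap-imputation parameters
#'
#' Stand-in gap filler: gaps bounded by nearly co-located fixes (within
#' `stationary_radius`) up to `stationary_gap_max` long are treated as dwells
#' and filled with the earlier position; shorter gaps up to `moving_gap_max`
#' are linearly interpolated; anything longer is left missing.
#'
#' @param stationary_gap_max Minutes (default 240).
#' @param stationary_radius Metres (default 100).
#' @param moving_gap_max Minutes (default 10).
#' @return An `imputation_params` list.
#' @export
imputation_params <- function(stationary_gap_max = 240,
                              stationary_radius = 100,
                              moving_gap_max = 10) {
  if (stationary_gap_max <= 0 || stationary_radius <= 0 || moving_gap_max <= 0) {
    stop("imputation parameters must be positive")
  }
  structure(list(stationary_gap_max = stationary_gap_max,
                 stationary_radius = stationary_radius,
                 moving_gap_max = moving_gap_max),
            class = "imputation_params")
}

#' Fill internal gaps in a GPS track
#'
#' For each internal gap between consecutive observed epochs more than 10 s
#' apart: if the bounding positions are within `stationary_radius` and the
#' gap is at most `stationary_gap_max`, every missing 10-s epoch is filled
#' with the earlier position; otherwise, if the gap is at most
#' `moving_gap_max`, missing epochs are linearly interpolated between the
#' bounding positions. Longer gaps, and leading/trailing missingness, are
#' never filled. Observed epochs are never moved. Idempotent.
#'
#' @param track A sorted `gps_track`.
#' @param params An [imputation_params()] object.
#' @return A `gps_track` with `imputed = TRUE` on filled epochs.
#' @export
impute_gaps <- function(track, params = imputation_params()) {
  stopifnot(inherits(track, "gps_track"))
  n <- nrow(track)
  if (n && any(diff(track$t) <= 0)) stop("track must be sorted")
  if (n < 2) return(track)
  meta <- track_meta(track)
  gaps <- which(diff(track$t) > 10L)
  fills <- lapply(gaps, function(i) {
    gap <- track$t[i + 1L] - track$t[i]
    tmiss <- seq(track$t[i] + 10L, track$t[i + 1L] - 10L, by = 10L)
    d <- sqrt((track$x[i + 1L] - track$x[i])^2 +
              (track$y[i + 1L] - track$y[i])^2)
    gap_min <- gap / 60
    if (d <= params$stationary_radius &&
        gap_min <= params$stationary_gap_max) {
      data.frame(t = tmiss, x = track$x[i], y = track$y[i], imputed = TRUE)
    } else if (gap_min <= params$moving_gap_max) {
      frac <- (tmiss - track$t[i]) / gap
      data.frame(
        t = tmiss,
        x = track$x[i] + frac * (track$x[i + 1L] - track$x[i]),
        y = track$y[i] + frac * (track$y[i + 1L] - track$y[i]),
        imputed = TRUE)
    } else {
      NULL
    }
  })
  out <- rbind(data.frame(t = track$t, x = track$x, y = track$y,
                          imputed = track$imputed),
               do.call(rbind, fills))
  out <- out[order(out$t), , drop = FALSE]
  gps_track(out$t, out$x, out$y, out$imputed,
            participant_id = meta$participant_id, wave = meta$wave,
            date = meta$date, day_type = meta$day_type)
}

#' GPS day validity
#'
#' Coverage is the total epoch count (observed plus imputed) converted to
#' hours; a day with less than 6 h of coverage after imputation is invalid
#' (exactly 6 h is valid).
#'
#' @param track A `gps_track` (imputation already applied).
#' @return List with `valid` (logical) and `coverage_hours`.
#' @export
gps_day_valid <- function(track) {
  stopifnot(inherits(track, "gps_track"))
  coverage <- nrow(track) * 10 / 3600
  list(valid = coverage >= 6, coverage_hours = coverage)
}
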