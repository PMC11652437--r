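# Person-day panel assembly and within/between decomposition.

#' Assemble the person-day analysis panel
#'
#' Inner-joins exposure rows and activity rows on (participant, wave, date),
#' drops days failing either the GPS or the accelerometer validity rule
#' (with a logged count by reason), and attaches person-level covariates and
#' the daily temperature.
#'
#' @param exposures Data.frame from [derive_day_exposures()] rows, plus a
#'   `gps_valid` column.
#' @param activity Data.frame from [process_accel_day()] rows
#'   (`accel_valid`, `wear_hours`, `mvpa_minutes`).
#' @param roster Participant covariates from [generate_participant_roster()]
#'   or equivalent.
#' @param temperature Data.frame with `date` and `temp_c`.
#' @param quiet Suppress the exclusion-count messages.
#' @return Data.frame, one row per retained person-day, with an
#'   `exclusions` attribute recording the row-count ledger.
#' @export
assemble_panel <- function(exposures, activity, roster, temperature = NULL,
                           quiet = FALSE) {
  key <- c("participant_id", "wave", "date")
  if (anyDuplicated(exposures[key]) || anyDuplicated(activity[key])) {
    stop("duplicate (participant, wave, date) keys")
  }
  merged <- merge(activity, exposures, by = key)
  n_accel <- nrow(activity)
  n_matched <- nrow(merged)
  drop_accel <- sum(!merged$accel_valid)
  merged <- merged[merged$accel_valid, , drop = FALSE]
  drop_gps <- if ("gps_valid" %in% names(merged)) {
    sum(!merged$gps_valid)
  } else 0L
  if ("gps_valid" %in% names(merged)) {
    merged <- merged[merged$gps_valid, , drop = FALSE]
  }
  excl <- c(accel_days = n_accel, matched = n_matched,
            removed_accel_invalid = drop_accel,
            removed_gps_invalid = drop_gps, final = nrow(merged))
  if (!quiet) {
    message(sprintf(
      "panel: %d accelerometer days, %d matched, -%d accel-invalid, -%d GPS-invalid, %d retained",
      n_accel, n_matched, drop_accel, drop_gps, nrow(merged)))
  }
  out <- merge(merged, roster, by = "participant_id")
  if (!is.null(temperature)) {
    out <- merge(out, temperature, by = "date")
  }
  out$weekend <- as.integer(out$day_type == "weekend")
  # distance enters the models per 100 m so all predictors share a scale
  out$park_distance_100m <- out$park_distance_m / 100
  out <- out[order(out$participant_id, out$wave, out$date), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  out
}

#' Log-transform the MVPA outcome
#'
#' `log(minutes + 1)`: defined at zero-MVPA days, invertible by
#' [back_transform_outcome()].
#'
#' @param mvpa_minutes Non-negative day-level MVPA minutes.
#' @param offset Offset added before the log (default 1).
#' @return Log-scale outcome.
#' @export
transform_outcome <- function(mvpa_minutes, offset = 1) {
  if (any(mvpa_minutes < 0)) stop("MVPA minutes must be non-negative")
  log(mvpa_minutes + offset)
}

#' @rdname transform_outcome
#' @param x Log-scale outcome values.
#' @export
back_transform_outcome <- function(x, offset = 1) {
  exp(x) - offset
}

#' Person-mean centering into between- and within-subject columns
#'
#' For each continuous variable, `<var>_bs` is the person mean centered on
#' the grand mean of person means and `<var>_ws` is the day's deviation
#' from the person mean (so `grand mean + person BS + day WS` reconstructs
#' the value exactly). The binary park indicator gets a centered
#' person-proportion BS term, while its WS term is by default the raw 0/1
#' day value for interpretability (set `center_binary = TRUE` for the
#' person-mean-centered variant).
#'
#' @param panel Data.frame with a `participant_id` column.
#' @param variables Continuous exposure columns to decompose.
#' @param binary Binary exposure column (default `"parks_any"`; `NULL` to
#'   skip).
#' @param center_binary Person-mean-center the binary WS term too.
#' @return The panel with `<var>_bs` / `<var>_ws` columns appended.
#' @export
person_mean_center <- function(panel,
                               variables = c("green_pct",
                                             "park_distance_100m",
                                             "walkability"),
                               binary = "parks_any",
                               center_binary = FALSE) {
  pid <- panel$participant_id
  for (v in c(variables, binary)) {
    if (!is.null(v) && !v %in% names(panel)) {
      stop("variable not in panel: ", v)
    }
  }
  for (v in variables) {
    pm <- stats::ave(panel[[v]], pid)
    grand <- mean(tapply(panel[[v]], pid, mean))
    panel[[paste0(v, "_bs")]] <- pm - grand
    panel[[paste0(v, "_ws")]] <- panel[[v]] - pm
  }
  if (!is.null(binary)) {
    pm <- stats::ave(panel[[binary]], pid)
    grand <- mean(tapply(panel[[binary]], pid, mean))
    panel[[paste0(binary, "_bs")]] <- pm - grand
    panel[[paste0(binary, "_ws")]] <- if (center_binary) {
      panel[[binary]] - pm
    } else {
      panel[[binary]]
    }
  }
  panel
}
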