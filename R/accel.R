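#' Accelerometer count series
#'
#' @param t Integer seconds since day start, strictly increasing on the 10-s
#'   lattice.
#' @param counts Non-negative integer activity counts per 10-s epoch.
#' @param participant_id,wave,date Metadata.
#' @return An `accel_series` (data.frame with attributes).
#' @export
accel_series <- function(t, counts, participant_id = NA_character_,
                         wave = NA_character_, date = NA_character_) {
  stopifnot(length(t) == length(counts))
  if (length(t)) {
    if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
    if (any(t %% 10 != 0)) stop("timestamps must lie on the 10-s lattice")
    if (any(counts < 0) || any(counts != round(counts))) {
      stop("counts must be non-negative integers")
    }
  }
  structure(data.frame(t = as.integer(t), counts = as.integer(counts)),
            class = c("accel_series", "data.frame"),
            participant_id = participant_id, wave = wave, date = date)
}

#' Read a one-day accelerometer stream from CSV
#'
#' Expects columns `timestamp_iso,counts`.
#'
#' @param path CSV file path.
#' @param participant_id,wave,date Metadata (defaults parsed from a
#'   `<pid>_<wave>_<day>.csv` filename).
#' @return An `accel_series`.
#' @export
read_accel_csv <- function(path, participant_id = NULL, wave = NULL,
                           date = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta <- parse_day_filename(path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!all(c("timestamp_iso", "counts") %in% names(raw))) {
    stop("expected header timestamp_iso,counts in ", path)
  }
  secs <- parse_iso_seconds(raw$timestamp_iso)
  cnt <- suppressWarnings(as.numeric(raw$counts))
  bad <- which(is.na(secs) | is.na(cnt))
  if (length(bad)) {
    stop(sprintf("unparseable accelerometer row at line %d of %s",
                 bad[1] + 1L, path))
  }
  o <- order(secs)
  accel_series(secs[o], cnt[o],
               participant_id = participant_id %||% meta$pid,
               wave = wave %||% meta$wave, date = date %||% meta$day)
}

#' Freedson cut-point parameters
#'
#' Energy expenditure is predicted from the per-minute count rate as
#' `METs = 1.439008 + 0.000795 * cpm`; epochs at or above `mvpa_threshold`
#' METs count as moderate-to-vigorous physical activity.
#'
#' @param intercept METs at zero counts (default 1.439008).
#' @param slope METs per count per minute (default 0.000795).
#' @param mvpa_threshold METs (default 4).
#' @return A `freedson_params` list.
#' @export
freedson_params <- function(intercept = 1.439008, slope = 0.000795,
                            mvpa_threshold = 4) {
  structure(list(intercept = intercept, slope = slope,
                 mvpa_threshold = mvpa_threshold),
            class = "freedson_params")
}

#' Predicted METs from counts per minute
#'
#' @param cpm Counts per minute (non-negative).
#' @param params A [freedson_params()] object.
#' @return Predicted METs.
#' @export
counts_to_mets <- function(cpm, params = freedson_params()) {
  if (any(cpm < 0)) stop("counts per minute must be non-negative")
  params$intercept + params$slope * cpm
}

#' Detect non-wear epochs
#'
#' An epoch is non-wear iff it lies in a maximal run of zero-count epochs
#' strictly longer than 60 minutes (more than 360 consecutive zero epochs);
#' exactly 60 minutes of zeros is still wear. A single non-zero epoch
#' restarts the run.
#'
#' @param series An `accel_series`.
#' @param min_minutes Run length threshold in minutes (default 60, strict).
#' @return Logical wear mask per epoch (`TRUE` = worn).
#' @export
detect_nonwear <- function(series, min_minutes = 60) {
  stopifnot(inherits(series, "accel_series"))
  n <- nrow(series)
  if (n == 0) return(logical(0))
  z <- series$counts == 0L
  r <- rle(z)
  run_id <- rep(seq_along(r$lengths), r$lengths)
  thr <- min_minutes * 6  # epochs
  nonwear_run <- r$values & r$lengths > thr
  !nonwear_run[run_id]
}

#' Accelerometer day validity
#'
#' Wear time is the wear-epoch count in hours; a day with less than 10 h of
#' wear is invalid (exactly 10 h is valid).
#'
#' @param series An `accel_series`.
#' @param wear_mask Logical mask from [detect_nonwear()].
#' @return List with `valid` and `wear_hours`.
#' @export
accel_day_valid <- function(series, wear_mask = detect_nonwear(series)) {
  stopifnot(nrow(series) == length(wear_mask))
  wear_hours <- sum(wear_mask) * 10 / 3600
  list(valid = wear_hours >= 10, wear_hours = wear_hours)
}

#' Classify epochs as MVPA
#'
#' Each 10-s epoch is scaled to a per-minute rate (`counts * 6`) and run
#' through the cut-point equation; wear epochs at or above the MET threshold
#' are MVPA. Non-wear epochs are never MVPA.
#'
#' @param series An `accel_series`.
#' @param wear_mask Logical wear mask.
#' @param params A [freedson_params()] object.
#' @return Logical MVPA mask per epoch.
#' @export
epoch_mvpa_mask <- function(series, wear_mask = detect_nonwear(series),
                            params = freedson_params()) {
  stopifnot(nrow(series) == length(wear_mask))
  mets <- counts_to_mets(series$counts * 6, params)
  wear_mask & mets >= params$mvpa_threshold
}

#' Day-level MVPA minutes
#'
#' @param mvpa_mask Logical mask from [epoch_mvpa_mask()].
#' @return MVPA epochs divided by 6 (minutes, possibly fractional).
#' @export
day_mvpa_minutes <- function(mvpa_mask) {
  sum(mvpa_mask) / 6
}

#' Process one accelerometer day end to end
#'
#' @param series An `accel_series`.
#' @param params A [freedson_params()] object.
#' @return One-row data.frame: `participant_id`, `wave`, `date`,
#'   `wear_hours`, `accel_valid`, `mvpa_minutes`.
#' @export
process_accel_day <- function(series, params = freedson_params()) {
  wear <- detect_nonwear(series)
  v <- accel_day_valid(series, wear)
  mv <- epoch_mvpa_mask(series, wear, params)
  data.frame(
    participant_id = attr(series, "participant_id"),
    wave = attr(series, "wave"),
    date = attr(series, "date"),
    wear_hours = v$wear_hours,
    accel_valid = v$valid,
    mvpa_minutes = day_mvpa_minutes(mv),
    stringsAsFactors = FALSE)
}
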