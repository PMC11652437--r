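# Daily exposure metrics: time-weighted overlay of an activity-space
# surface on a gridded environmental layer.

#' Time-weighted exposure to a gridded environmental variable
#'
#' The daily exposure is the weighted sum over cells of the layer value
#' times the fraction of the day's time spent in the cell. Nodata cells are
#' handled either by renormalizing the time weights over defined cells
#' (default, appropriate when the variable is undefined off the street
#' network) or by treating nodata as zero.
#'
#' @param surface A `time_weight_grid`.
#' @param layer An `env_layer` on the same `grid_spec` (asserted; no silent
#'   resampling).
#' @param nodata_policy `"renormalize"` (default) or `"zero"`.
#' @return The scalar exposure value; `NA` (with a warning) if all time
#'   weight falls on nodata cells under the renormalize policy.
#' @export
weighted_exposure <- function(surface, layer,
                              nodata_policy = c("renormalize", "zero")) {
  nodata_policy <- match.arg(nodata_policy)
  stopifnot(inherits(surface, "time_weight_grid"), inherits(layer, "env_layer"))
  assert_same_grid(surface$grid, layer$grid)
  w <- surface$weights
  v <- layer$values
  defined <- !is.na(v)
  if (nodata_policy == "zero") {
    v[!defined] <- 0
    return(sum(w * v))
  }
  wd <- sum(w[defined])
  if (wd == 0) {
    warning("all time weight falls on nodata cells; exposure undefined")
    return(NA_real_)
  }
  sum(w[defined] * v[defined]) / wd
}

#' Any park/open-space exposure in a daily surface
#'
#' Yes iff any cell with strictly positive time weight is a park cell;
#' equivalent to a strictly positive weighted park-indicator exposure.
#'
#' @param surface A `time_weight_grid`.
#' @param parks An `env_layer` of variable `park_indicator` on the same grid.
#' @return Logical.
#' @export
parks_any_exposure <- function(surface, parks) {
  stopifnot(inherits(parks, "env_layer"), parks$variable == "park_indicator")
  assert_same_grid(surface$grid, parks$grid)
  any(surface$weights > 0 & parks$values == 1)
}

#' Derive all four daily exposure metrics for one GPS day
#'
#' Builds the activity-space surface by the requested method on the
#' environment bundle's grid and evaluates street-level greenspace coverage,
#' distance to the nearest park entrance, any park/open-space exposure, and
#' the walkability index as time-weighted overlays.
#'
#' @param track A valid `gps_track`.
#' @param env An `environment_bundle` from [generate_environment()] (or any
#'   list with `grid`, `greenspace_layer`, `park_distance_layer`,
#'   `parks_layer`, `walkability_layer`, `streets`, and, for residential
#'   mode, a `homes` table).
#' @param method `"kde"`, `"daily_path"`, or `"residential_buffer"`.
#' @param bandwidth KDE bandwidth, metres (default 250).
#' @param radius Daily-path or residential buffer radius, metres.
#' @param residential_mode `"euclidean"` or `"network"`.
#' @param home Numeric `c(x, y)`; required for residential mode (defaults
#'   to the participant's home in `env$homes`).
#' @param nodata_policy Passed to [weighted_exposure()].
#' @return One-row data.frame: identifiers, method tag, parameter, and the
#'   four metrics (`green_pct`, `park_distance_m`, `parks_any`,
#'   `walkability`).
#' @export
derive_day_exposures <- function(track, env,
                                 method = c("kde", "daily_path",
                                            "residential_buffer"),
                                 bandwidth = 250, radius = 250,
                                 residential_mode = "euclidean",
                                 home = NULL,
                                 nodata_policy = "renormalize") {
  method <- match.arg(method)
  meta <- track_meta(track)
  surface <- switch(method,
    kde = kde_surface(track, env$grid, bandwidth = bandwidth),
    daily_path = daily_path_surface(track, env$grid, radius = radius),
    residential_buffer = {
      if (is.null(home)) {
        if (is.null(env$homes)) stop("residential mode needs a home location")
        i <- match(meta$participant_id, env$homes$participant_id)
        if (is.na(i)) stop("no home on record for ", meta$participant_id)
        home <- c(env$homes$x[i], env$homes$y[i])
      }
      residential_buffer_surface(home, env$grid, radius = radius,
                                 mode = residential_mode,
                                 streets = env$streets)
    })
  param <- if (method == "kde") bandwidth else radius
  data.frame(
    participant_id = meta$participant_id,
    wave = meta$wave,
    date = meta$date,
    day_type = meta$day_type,
    method = method,
    param_m = param,
    green_pct = weighted_exposure(surface, env$greenspace_layer,
                                  nodata_policy = nodata_policy),
    park_distance_m = weighted_exposure(surface, env$park_distance_layer),
    parks_any = as.integer(parks_any_exposure(surface, env$parks_layer)),
    walkability = weighted_exposure(surface, env$walkability_layer),
    stringsAsFactors = FALSE)
}
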