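# Minimal GeoJSON writers for the synthetic study's vector interchange
# files (planar coordinates on the local synthetic CRS).

#' @keywords internal
geojson_feature <- function(geometry, properties) {
  list(type = "Feature", geometry = geometry,
       properties = if (length(properties)) properties else NULL)
}

#' Write point features as GeoJSON
#'
#' @param df Data.frame with `x`, `y` and any property columns.
#' @param path Output path.
#' @export
write_geojson_points <- function(df, path) {
  props <- setdiff(names(df), c("x", "y"))
  feats <- lapply(seq_len(nrow(df)), function(i) {
    geojson_feature(
      list(type = "Point", coordinates = c(df$x[i], df$y[i])),
      as.list(df[i, props, drop = FALSE]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write line-segment features as GeoJSON
#'
#' @param segments Data.frame with `x0`, `y0`, `x1`, `y1` and property
#'   columns.
#' @param path Output path.
#' @export
write_geojson_lines <- function(segments, path) {
  props <- setdiff(names(segments), c("x0", "y0", "x1", "y1"))
  feats <- lapply(seq_len(nrow(segments)), function(i) {
    geojson_feature(
      list(type = "LineString",
           coordinates = list(c(segments$x0[i], segments$y0[i]),
                              c(segments$x1[i], segments$y1[i]))),
      as.list(segments[i, props, drop = FALSE]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write rectangle polygons as GeoJSON
#'
#' @param rects Data.frame with `xmin`, `xmax`, `ymin`, `ymax` and property
#'   columns.
#' @param path Output path.
#' @export
write_geojson_rectangles <- function(rects, path) {
  props <- setdiff(names(rects), c("xmin", "xmax", "ymin", "ymax"))
  feats <- lapply(seq_len(nrow(rects)), function(i) {
    ring <- list(c(rects$xmin[i], rects$ymin[i]),
                 c(rects$xmax[i], rects$ymin[i]),
                 c(rects$xmax[i], rects$ymax[i]),
                 c(rects$xmin[i], rects$ymax[i]),
                 c(rects$xmin[i], rects$ymin[i]))
    geojson_feature(list(type = "Polygon", coordinates = list(ring)),
                    as.list(rects[i, props, drop = FALSE]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
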