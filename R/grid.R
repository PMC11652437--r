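#' Analysis grid specification
#'
#' A `grid_spec` describes the regular square grid on which activity-space
#' surfaces and environmental layers live. Cell `(r, c)` (0-based, row 0 the
#' southernmost row) covers the half-open square
#' `[origin_x + c*s, origin_x + (c+1)*s) x [origin_y + r*s, origin_y + (r+1)*s)`.
#' Matrices indexed by a `grid_spec` store row 0 in matrix row 1, so
#' `m[r + 1, c + 1]` is cell `(r, c)`.
#'
#' @param origin_x,origin_y Lower-left corner, metres.
#' @param cell_size Cell edge length, metres (default 50).
#' @param nrows,ncols Grid dimensions.
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(origin_x, origin_y, cell_size = 50, nrows, ncols) {
  stopifnot(is.numeric(cell_size), length(cell_size) == 1)
  if (!is.finite(cell_size) || cell_size <= 0) {
    stop("cell_size must be a positive number")
  }
  if (nrows < 1 || ncols < 1) stop("grid must have at least one cell")
  structure(
    list(origin_x = origin_x, origin_y = origin_y, cell_size = cell_size,
         nrows = as.integer(nrows), ncols = as.integer(ncols)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g m, origin (%g, %g)\n",
              x$nrows, x$ncols, x$cell_size, x$origin_x, x$origin_y))
  invisible(x)
}

#' Build a grid covering an extent, padded and snapped
#'
#' The grid is expanded by `pad` on every side (default: the KDE bandwidth,
#' so no kernel mass is clipped) and the origin is snapped down to a multiple
#' of `cell_size`, so grids built independently over overlapping extents
#' align cell-for-cell.
#'
#' @param extent Numeric vector `c(xmin, xmax, ymin, ymax)`, metres.
#' @param cell_size Cell edge length, metres (default 50).
#' @param pad Padding added to every side, metres (default 250).
#' @return A `grid_spec`.
#' @export
make_grid_spec <- function(extent, cell_size = 50, pad = 250) {
  stopifnot(length(extent) == 4)
  if (!is.finite(cell_size) || cell_size <= 0) stop("cell_size must be > 0")
  if (extent[2] <= extent[1] || extent[4] <= extent[3]) {
    stop("extent is degenerate")
  }
  x0 <- floor((extent[1] - pad) / cell_size) * cell_size
  y0 <- floor((extent[3] - pad) / cell_size) * cell_size
  ncols <- ceiling((extent[2] + pad - x0) / cell_size)
  nrows <- ceiling((extent[4] + pad - y0) / cell_size)
  grid_spec(x0, y0, cell_size, nrows, ncols)
}

#' Cell-center coordinates of a grid
#'
#' @param grid A `grid_spec`.
#' @return List with `x` (length ncols) and `y` (length nrows) center
#'   coordinates; `y[1]` is the southernmost row.
#' @export
cell_centers <- function(grid) {
  s <- grid$cell_size
  list(
    x = grid$origin_x + (seq_len(grid$ncols) - 0.5) * s,
    y = grid$origin_y + (seq_len(grid$nrows) - 0.5) * s
  )
}

#' @keywords internal
same_grid <- function(a, b, tol = 1e-9) {
  abs(a$origin_x - b$origin_x) < tol && abs(a$origin_y - b$origin_y) < tol &&
    abs(a$cell_size - b$cell_size) < tol &&
    a$nrows == b$nrows && a$ncols == b$ncols
}

#' @keywords internal
assert_same_grid <- function(a, b) {
  if (!same_grid(a, b)) {
    stop("grid specs do not match; no silent resampling is performed")
  }
  invisible(TRUE)
}

#' Time-weighted activity-space surface
#'
#' Cell weights are fractions of the day's time; the constructor enforces
#' non-negativity and unit total mass.
#'
#' @param grid A `grid_spec`.
#' @param weights Numeric matrix `nrows x ncols` of non-negative weights
#'   summing to 1 (within 1e-9; renormalized exactly).
#' @param method One of `"kde"`, `"daily_path"`, `"residential_buffer"`.
#' @param bandwidth_or_radius Metres; the kernel bandwidth or buffer radius.
#' @return A `time_weight_grid`.
#' @export
time_weight_grid <- function(grid, weights, method, bandwidth_or_radius) {
  method <- match.arg(method, c("kde", "daily_path", "residential_buffer"))
  stopifnot(inherits(grid, "grid_spec"), is.matrix(weights))
  if (nrow(weights) != grid$nrows || ncol(weights) != grid$ncols) {
    stop("weights matrix does not match grid dimensions")
  }
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop("weights must be finite and non-negative")
  }
  tot <- sum(weights)
  if (abs(tot - 1) > 1e-9) {
    stop(sprintf("weights sum to %.12f, not 1 within 1e-9", tot))
  }
  structure(
    list(grid = grid, weights = weights / tot, method = method,
         bandwidth_or_radius = bandwidth_or_radius),
    class = "time_weight_grid"
  )
}

#' @export
print.time_weight_grid <- function(x, ...) {
  cat(sprintf("<time_weight_grid> method=%s (%g m), %d x %d cells, %d with mass\n",
              x$method, x$bandwidth_or_radius, x$grid$nrows, x$grid$ncols,
              sum(x$weights > 0)))
  invisible(x)
}

#' Gridded environmental layer
#'
#' @param grid A `grid_spec`.
#' @param values Numeric matrix `nrows x ncols`; `NA` marks nodata cells.
#' @param variable One of `"green_pct"`, `"park_distance_m"`,
#'   `"park_indicator"`, `"walkability"`.
#' @return An `env_layer`.
#' @export
env_layer <- function(grid, values, variable) {
  variable <- match.arg(variable, c("green_pct", "park_distance_m",
                                    "park_indicator", "walkability"))
  stopifnot(inherits(grid, "grid_spec"), is.matrix(values))
  if (nrow(values) != grid$nrows || ncol(values) != grid$ncols) {
    stop("values matrix does not match grid dimensions")
  }
  v <- values[!is.na(values)]
  ok <- switch(variable,
    green_pct = all(v >= 0 & v <= 100),
    park_distance_m = all(v >= 0),
    park_indicator = all(v %in% c(0, 1)),
    walkability = all(v >= 1 & v <= 20)
  )
  if (!ok) stop(sprintf("values out of range for variable '%s'", variable))
  structure(list(grid = grid, values = values, variable = variable),
            class = "env_layer")
}

#' @export
print.env_layer <- function(x, ...) {
  cat(sprintf("<env_layer> %s, %d x %d cells, %d nodata\n",
              x$variable, x$grid$nrows, x$grid$ncols, sum(is.na(x$values))))
  invisible(x)
}

#' Write a gridded matrix as an Esri ASCII grid
#'
#' @param grid A `grid_spec`.
#' @param values Numeric matrix (`NA` written as the nodata value).
#' @param path Output file path.
#' @param nodata Nodata sentinel (default -9999).
#' @export
write_esri_ascii <- function(grid, values, path, nodata = -9999) {
  stopifnot(inherits(grid, "grid_spec"), is.matrix(values))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid$ncols),
    sprintf("nrows %d", grid$nrows),
    sprintf("xllcorner %.10g", grid$origin_x),
    sprintf("yllcorner %.10g", grid$origin_y),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %g", nodata)
  ), con)
  v <- values
  v[is.na(v)] <- nodata
  # rows are written north to south
  for (r in rev(seq_len(grid$nrows))) {
    writeLines(paste(formatC(v[r, ], format = "g", digits = 15),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read an Esri ASCII grid
#'
#' @param path File written by [write_esri_ascii()] or any conforming source.
#' @return List with `grid` (a `grid_spec`) and `values` (matrix, `NA` for
#'   nodata, matrix row 1 = southernmost row).
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) stop("malformed Esri ASCII header")
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  body <- lines[i:length(lines)]
  vals <- as.numeric(unlist(strsplit(trimws(body), "\\s+")))
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) stop("Esri ASCII body size mismatch")
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[rev(seq_len(nr)), , drop = FALSE]  # back to south-first rows
  m[m == nodata] <- NA
  list(grid = grid_spec(hdr$xllcorner, hdr$yllcorner, hdr$cellsize, nr, nc),
       values = m)
}
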