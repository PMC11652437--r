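# Gridding of environmental source data to the analysis grid.

# Length of segment AB lying within the disc of radius R around each point
# (px, py). Vectorized over points; closed form from the quadratic
# |A + t(B-A) - P|^2 = R^2 intersected with t in [0, 1].
#' @keywords internal
chord_length_in_disc <- function(px, py, ax, ay, bx, by, R) {
  dx <- bx - ax; dy <- by - ay
  a <- dx^2 + dy^2
  if (a == 0) return(rep(0, length(px)))
  b <- 2 * ((ax - px) * dx + (ay - py) * dy)
  cc <- (ax - px)^2 + (ay - py)^2 - R^2
  disc <- b^2 - 4 * a * cc
  out <- numeric(length(px))
  pos <- disc > 0
  if (any(pos)) {
    sq <- sqrt(disc[pos])
    t0 <- pmax(0, (-b[pos] - sq) / (2 * a))
    t1 <- pmin(1, (-b[pos] + sq) / (2 * a))
    out[pos] <- pmax(0, t1 - t0) * sqrt(a)
  }
  out
}

# Distance from points to segment AB, vectorized over points.
#' @keywords internal
dist_to_segment <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len2 <- dx^2 + dy^2
  if (len2 == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / len2))
  sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
}

#' Grid street-level greenspace percentages
#'
#' Streets are buffered by `buffer` metres on each side; a cell whose center
#' falls within the buffer of at least one segment takes the length-weighted
#' mean greenspace percentage of the contributing segments, each segment
#' weighted by its length within `weight_radius` metres of the cell center.
#' Cells outside every street buffer are nodata.
#'
#' @param streets A `street_lattice` whose `segments` carry a `green_pct`
#'   column, or a data.frame of segments (x0, y0, x1, y1, green_pct).
#' @param grid A `grid_spec`.
#' @param buffer Half-width of the street buffer, metres (default 25).
#' @param weight_radius Radius of the length-weighting disc, metres
#'   (default 50).
#' @return An `env_layer` of variable `green_pct`.
#' @export
rasterize_street_greenspace <- function(streets, grid, buffer = 25,
                                        weight_radius = 50) {
  segs <- if (inherits(streets, "street_lattice")) streets$segments else streets
  if (is.null(segs$green_pct)) stop("segments must carry a green_pct column")
  if (nrow(segs) == 0) stop("empty street set")
  if (any(segs$green_pct < 0 | segs$green_pct > 100)) {
    stop("green_pct must lie in [0, 100]")
  }
  s <- grid$cell_size
  num <- matrix(0, grid$nrows, grid$ncols)
  den <- matrix(0, grid$nrows, grid$ncols)
  for (i in seq_len(nrow(segs))) {
    ax <- segs$x0[i]; ay <- segs$y0[i]
    bx <- segs$x1[i]; by <- segs$y1[i]
    c0 <- max(0L, floor((min(ax, bx) - buffer - grid$origin_x) / s))
    c1 <- min(grid$ncols - 1L, floor((max(ax, bx) + buffer - grid$origin_x) / s))
    r0 <- max(0L, floor((min(ay, by) - buffer - grid$origin_y) / s))
    r1 <- min(grid$nrows - 1L, floor((max(ay, by) + buffer - grid$origin_y) / s))
    if (c0 > c1 || r0 > r1) next
    cxs <- grid$origin_x + ((c0:c1) + 0.5) * s
    cys <- grid$origin_y + ((r0:r1) + 0.5) * s
    px <- rep(cxs, each = length(cys))
    py <- rep(cys, times = length(cxs))
    near <- dist_to_segment(px, py, ax, ay, bx, by) <= buffer
    if (!any(near)) next
    wl <- chord_length_in_disc(px[near], py[near], ax, ay, bx, by,
                               weight_radius)
    rr <- rep(r0:r1, times = length(cxs))[near] + 1L
    cc <- rep(c0:c1, each = length(cys))[near] + 1L
    idx <- cbind(rr, cc)
    num[idx] <- num[idx] + wl * segs$green_pct[i]
    den[idx] <- den[idx] + wl
  }
  vals <- matrix(NA_real_, grid$nrows, grid$ncols)
  ok <- den > 0
  vals[ok] <- num[ok] / den[ok]
  env_layer(grid, vals, "green_pct")
}

#' Grid distance to the nearest park entrance
#'
#' Euclidean mode computes the straight-line distance from each cell center
#' to its nearest entrance. Network mode walks the street lattice: the
#' distance is the shortest-path distance from the cell center's snapped
#' node to the entrance's snapped node, plus the cell center's snap offset.
#'
#' @param entrances Data.frame with columns `x`, `y` (at least one row).
#' @param grid A `grid_spec`.
#' @param mode `"euclidean"` or `"network"`.
#' @param streets A `street_lattice`, required in network mode.
#' @return An `env_layer` of variable `park_distance_m`.
#' @export
park_distance_layer <- function(entrances, grid,
                                mode = c("euclidean", "network"),
                                streets = NULL) {
  mode <- match.arg(mode)
  if (is.null(entrances) || nrow(entrances) == 0) {
    stop("at least one park entrance is required")
  }
  ctr <- cell_centers(grid)
  if (mode == "euclidean") {
    best <- matrix(Inf, grid$nrows, grid$ncols)
    for (i in seq_len(nrow(entrances))) {
      d <- sqrt(outer((ctr$y - entrances$y[i])^2,
                      (ctr$x - entrances$x[i])^2, `+`))
      best <- pmin(best, d)
    }
  } else {
    if (is.null(streets)) stop("network mode requires a street lattice")
    nd <- rep(Inf, nrow(streets$nodes))
    for (i in seq_len(nrow(entrances))) {
      nd <- pmin(nd, lattice_node_distances(streets, entrances$x[i],
                                            entrances$y[i]))
    }
    # snap every cell center to its nearest lattice node
    block <- streets$block
    k <- as.integer(streets$extent / block)
    nix <- pmin(k, pmax(0L, as.integer(round(ctr$x / block))))
    niy <- pmin(k, pmax(0L, as.integer(round(ctr$y / block))))
    best <- matrix(0, grid$nrows, grid$ncols)
    for (r in seq_len(grid$nrows)) {
      node <- niy[r] * (k + 1L) + nix + 1L
      off <- sqrt((ctr$x - nix * block)^2 + (ctr$y[r] - niy[r] * block)^2)
      best[r, ] <- nd[node] + off
    }
  }
  env_layer(grid, best, "park_distance_m")
}

#' Grid park polygons to a binary indicator
#'
#' A cell is a park cell (value 1) iff its center lies inside any park
#' rectangle; membership uses the half-open convention (closed on the
#' south/west edge, open on the north/east edge) so adjoining parks never
#' double-count a boundary.
#'
#' @param parks Data.frame of axis-aligned rectangles with columns
#'   `xmin`, `xmax`, `ymin`, `ymax` (may have zero rows: no parks).
#' @param grid A `grid_spec`.
#' @return An `env_layer` of variable `park_indicator`.
#' @export
rasterize_parks <- function(parks, grid) {
  if (!is.null(parks) && nrow(parks) > 0 &&
      any(parks$xmax <= parks$xmin | parks$ymax <= parks$ymin)) {
    stop("invalid park rectangle geometry")
  }
  ctr <- cell_centers(grid)
  vals <- matrix(0, grid$nrows, grid$ncols)
  if (!is.null(parks)) {
    for (i in seq_len(nrow(parks))) {
      inx <- ctr$x >= parks$xmin[i] & ctr$x < parks$xmax[i]
      iny <- ctr$y >= parks$ymin[i] & ctr$y < parks$ymax[i]
      vals[iny, inx] <- 1
    }
  }
  env_layer(grid, vals, "park_indicator")
}

#' Grid tract-level walkability scores
#'
#' Each cell takes the score of the tract patch containing its center
#' (half-open membership). Cells in no patch are nodata.
#'
#' @param patches Data.frame of axis-aligned rectangles with columns
#'   `xmin`, `xmax`, `ymin`, `ymax`, `score` (scores in `[1, 20]`).
#' @param grid A `grid_spec`.
#' @return An `env_layer` of variable `walkability`.
#' @export
rasterize_walkability <- function(patches, grid) {
  if (nrow(patches) == 0) stop("empty patch set")
  if (any(patches$score < 1 | patches$score > 20)) {
    stop("walkability scores must lie in [1, 20]")
  }
  ctr <- cell_centers(grid)
  vals <- matrix(NA_real_, grid$nrows, grid$ncols)
  for (i in seq_len(nrow(patches))) {
    inx <- ctr$x >= patches$xmin[i] & ctr$x < patches$xmax[i]
    iny <- ctr$y >= patches$ymin[i] & ctr$y < patches$ymax[i]
    vals[iny, inx] <- patches$score[i]
  }
  env_layer(grid, vals, "walkability")
}
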