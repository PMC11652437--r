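# Activity-space surfaces: KDE (primary), daily path area, residential
# buffers. All three return a time_weight_grid whose weights sum to 1.

#' Time-weighted kernel density activity-space surface
#'
#' Each 10-s epoch (observed or imputed) contributes one unit of time mass,
#' spread over nearby cell centers by a kernel of bandwidth `h`. Per-epoch
#' kernel values are normalized to sum to 1 over in-grid cells before
#' accumulation, so every epoch carries exactly one epoch's worth of time
#' and edge clipping cannot distort relative time weights. The default
#' kernel is the quartic (biweight) `K(d) proportional to (1 - (d/h)^2)^2`
#' for `d < h`; a Gaussian truncated at `h` is available.
#'
#' @param track A `gps_track` (should pass [gps_day_valid()]).
#' @param grid A `grid_spec`; should pad at least `bandwidth` beyond the
#'   track's bounding box.
#' @param bandwidth Kernel bandwidth, metres (default 250).
#' @param kernel `"quartic"` (default) or `"gaussian"`.
#' @return A `time_weight_grid` with `method = "kde"`.
#' @export
kde_surface <- function(track, grid, bandwidth = 250, kernel = "quartic") {
  kernel <- match.arg(kernel, c("quartic", "gaussian"))
  stopifnot(inherits(track, "gps_track"), inherits(grid, "grid_spec"))
  if (nrow(track) == 0) stop("cannot build a KDE surface from an empty track")
  if (bandwidth <= 0) stop("bandwidth must be positive")
  s <- grid$cell_size
  h2 <- bandwidth^2
  px <- track$x; py <- track$y
  ci <- as.integer(floor((px - grid$origin_x) / s))  # 0-based epoch col
  ri <- as.integer(floor((py - grid$origin_y) / s))
  K <- as.integer(ceiling(bandwidth / s)) + 1L
  offs <- expand.grid(dr = -K:K, dc = -K:K)
  n <- length(px)
  m <- nrow(offs)
  kern <- matrix(0, n, m)
  rows <- matrix(0L, n, m)
  cols <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    r <- ri + offs$dr[j]
    c <- ci + offs$dc[j]
    cx <- grid$origin_x + (c + 0.5) * s
    cy <- grid$origin_y + (r + 0.5) * s
    d2 <- (px - cx)^2 + (py - cy)^2
    inside <- (d2 < h2) & r >= 0L & r < grid$nrows & c >= 0L &
      c < grid$ncols
    kv <- if (kernel == "quartic") {
      u <- 1 - d2 / h2
      inside * u * u
    } else {
      inside * exp(-d2 / (2 * (bandwidth / 3)^2))
    }
    kern[, j] <- kv
    rows[, j] <- r
    cols[, j] <- c
  }
  rs <- rowSums(kern)
  # an epoch whose kernel misses every in-grid cell center puts its whole
  # epoch of time in its own cell (only possible for h << cell size)
  degenerate <- which(rs == 0)
  for (i in degenerate) {
    r <- min(max(ri[i], 0L), grid$nrows - 1L)
    c <- min(max(ci[i], 0L), grid$ncols - 1L)
    kern[i, 1] <- 1; rows[i, 1] <- r; cols[i, 1] <- c
    rs[i] <- 1
  }
  kern <- kern / rs
  idx <- cols * grid$nrows + rows + 1L  # column-major linear index
  storage.mode(idx) <- "integer"
  keep <- kern > 0
  acc <- numeric(grid$nrows * grid$ncols)
  tab <- rowsum(kern[keep], idx[keep])
  acc[as.integer(rownames(tab))] <- tab
  w <- matrix(acc / n, grid$nrows, grid$ncols)
  time_weight_grid(grid, w / sum(w), "kde", bandwidth)
}

# Mark cells of `covered` whose centers lie within `r` of segment AB.
#' @keywords internal
mark_capsule <- function(covered, grid, ax, ay, bx, by, r) {
  s <- grid$cell_size
  xmin <- min(ax, bx) - r; xmax <- max(ax, bx) + r
  ymin <- min(ay, by) - r; ymax <- max(ay, by) + r
  c0 <- max(0L, floor((xmin - grid$origin_x) / s))
  c1 <- min(grid$ncols - 1L, floor((xmax - grid$origin_x) / s))
  r0 <- max(0L, floor((ymin - grid$origin_y) / s))
  r1 <- min(grid$nrows - 1L, floor((ymax - grid$origin_y) / s))
  if (c0 > c1 || r0 > r1) return(covered)
  cxs <- grid$origin_x + ((c0:c1) + 0.5) * s
  cys <- grid$origin_y + ((r0:r1) + 0.5) * s
  px <- rep(cxs, each = length(cys))
  py <- rep(cys, times = length(cxs))
  dx <- bx - ax; dy <- by - ay
  len2 <- dx^2 + dy^2
  if (len2 == 0) {
    d2 <- (px - ax)^2 + (py - ay)^2
  } else {
    t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / len2))
    d2 <- (px - (ax + t * dx))^2 + (py - (ay + t * dy))^2
  }
  hit <- d2 <= r^2
  if (any(hit)) {
    rr <- rep(r0:r1, times = length(cxs))[hit] + 1L
    cc <- rep(c0:c1, each = length(cys))[hit] + 1L
    covered[cbind(rr, cc)] <- TRUE
  }
  covered
}

# Batched mark_capsule: cells within r of any of the segments (A_i, B_i).
#' @keywords internal
mark_capsules <- function(covered, grid, ax, ay, bx, by, r) {
  s <- grid$cell_size
  c0 <- max(0L, floor((min(ax, bx) - r - grid$origin_x) / s))
  c1 <- min(grid$ncols - 1L, floor((max(ax, bx) + r - grid$origin_x) / s))
  r0 <- max(0L, floor((min(ay, by) - r - grid$origin_y) / s))
  r1 <- min(grid$nrows - 1L, floor((max(ay, by) + r - grid$origin_y) / s))
  if (c0 > c1 || r0 > r1) return(covered)
  cxs <- grid$origin_x + ((c0:c1) + 0.5) * s
  cys <- grid$origin_y + ((r0:r1) + 0.5) * s
  px <- rep(cxs, each = length(cys))
  py <- rep(cys, times = length(cxs))
  m <- length(px)
  dx <- bx - ax; dy <- by - ay
  len2 <- pmax(dx^2 + dy^2, 1e-300)
  pxa <- outer(px, ax, `-`)
  pya <- outer(py, ay, `-`)
  tt <- (pxa * rep(dx, each = m) + pya * rep(dy, each = m)) /
    rep(len2, each = m)
  tt[tt < 0] <- 0; tt[tt > 1] <- 1
  d2 <- (pxa - tt * rep(dx, each = m))^2 +
    (pya - tt * rep(dy, each = m))^2
  hit <- rowSums(d2 <= r^2) > 0
  if (any(hit)) {
    rr <- rep(r0:r1, times = length(cxs))[hit] + 1L
    cc <- rep(c0:c1, each = length(cys))[hit] + 1L
    covered[cbind(rr, cc)] <- TRUE
  }
  covered
}

#' Daily path area activity-space surface
#'
#' Connects successive GPS epochs into route polylines (pieces are broken
#' where consecutive epochs are more than `gap_break_min` apart, so no
#' corridor is fabricated across unobserved periods), buffers the routes by
#' `radius`, and assigns equal weight to every cell whose center falls in
#' the buffer. A single-epoch track degenerates to a disc around the point.
#'
#' @param track A `gps_track`.
#' @param grid A `grid_spec`.
#' @param radius Buffer radius, metres (default 250).
#' @param gap_break_min Observed gaps longer than this many minutes split
#'   the route (default 5).
#' @return A `time_weight_grid` with `method = "daily_path"`.
#' @export
daily_path_surface <- function(track, grid, radius = 250, gap_break_min = 5) {
  stopifnot(inherits(track, "gps_track"), inherits(grid, "grid_spec"))
  if (nrow(track) == 0) stop("cannot buffer an empty track")
  if (radius <= 0) stop("radius must be positive")
  covered <- matrix(FALSE, grid$nrows, grid$ncols)
  piece_id <- c(0, cumsum(diff(track$t) > gap_break_min * 60))
  for (p in unique(piece_id)) {
    seg <- track[piece_id == p, , drop = FALSE]
    if (nrow(seg) == 1) {
      covered <- mark_capsule(covered, grid, seg$x, seg$y, seg$x, seg$y,
                              radius)
      next
    }
    # capsules for chunks of consecutive segments, vectorized over
    # (candidate cells x segments)
    n_seg <- nrow(seg) - 1L
    for (lo in seq(1L, n_seg, by = 200L)) {
      hi <- min(lo + 199L, n_seg)
      covered <- mark_capsules(covered, grid,
                               seg$x[lo:hi], seg$y[lo:hi],
                               seg$x[(lo + 1L):(hi + 1L)],
                               seg$y[(lo + 1L):(hi + 1L)], radius)
    }
  }
  nc <- sum(covered)
  if (nc == 0) stop("buffer covers no cell center; grid too coarse")
  w <- matrix(0, grid$nrows, grid$ncols)
  w[covered] <- 1 / nc
  time_weight_grid(grid, w, "daily_path", radius)
}

#' Residential buffer activity-space surface
#'
#' Euclidean mode covers every cell center within `radius` of the home;
#' network mode computes the street-network service area (all points of the
#' lattice within network distance `radius` of the snapped home node,
#' including partial edges) and buffers it by one block width. Weights are
#' uniform over covered cells.
#'
#' @param home Numeric `c(x, y)`, metres; must lie inside the grid.
#' @param grid A `grid_spec`.
#' @param radius Buffer radius, metres (800 or 1600 in the study design).
#' @param mode `"euclidean"` or `"network"`.
#' @param streets A `street_lattice`, required in network mode.
#' @return A `time_weight_grid` with `method = "residential_buffer"`.
#' @export
residential_buffer_surface <- function(home, grid, radius = 800,
                                       mode = c("euclidean", "network"),
                                       streets = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "grid_spec"), length(home) == 2)
  if (radius <= 0) stop("radius must be positive")
  ctr <- cell_centers(grid)
  if (home[1] < grid$origin_x || home[1] > grid$origin_x + grid$ncols * grid$cell_size ||
      home[2] < grid$origin_y || home[2] > grid$origin_y + grid$nrows * grid$cell_size) {
    stop("home lies outside the grid")
  }
  if (mode == "euclidean") {
    d2 <- outer(ctr$y - home[2], ctr$x - home[1],
                function(a, b) a^2 + b^2)
    covered <- d2 <= radius^2
  } else {
    if (is.null(streets)) stop("network mode requires a street lattice")
    d <- lattice_node_distances(streets, home[1], home[2])
    covered <- matrix(FALSE, grid$nrows, grid$ncols)
    segs <- streets$segments
    du <- d[streets$edge_from]
    dv <- d[streets$edge_to]
    for (i in seq_len(nrow(segs))) {
      if (du[i] > radius && dv[i] > radius) next
      len <- segs$length[i]
      ux <- segs$x0[i]; uy <- segs$y0[i]
      vx <- segs$x1[i]; vy <- segs$y1[i]
      # reachable sub-segment from the u end
      if (du[i] <= radius) {
        f <- min(1, (radius - du[i]) / len)
        covered <- mark_capsule(covered, grid, ux, uy,
                                ux + f * (vx - ux), uy + f * (vy - uy),
                                streets$block)
      }
      # reachable sub-segment from the v end
      if (dv[i] <= radius) {
        f <- min(1, (radius - dv[i]) / len)
        covered <- mark_capsule(covered, grid, vx, vy,
                                vx + f * (ux - vx), vy + f * (uy - vy),
                                streets$block)
      }
    }
  }
  nc <- sum(covered)
  if (nc == 0) stop("buffer covers no cell center")
  w <- matrix(0, grid$nrows, grid$ncols)
  w[covered] <- 1 / nc
  time_weight_grid(grid, w, "residential_buffer", radius)
}

#' Write an activity-space surface as an Esri ASCII grid with sidecar
#'
#' The weights go to `<path>.asc`; the method, parameter and cell size go
#' to a `<path>.yaml` sidecar so a surface on disk is self-describing.
#'
#' @param surface A `time_weight_grid`.
#' @param path Output path stem (extensions are appended).
#' @return Invisibly, the two file paths.
#' @export
write_surface_asc <- function(surface, path) {
  stopifnot(inherits(surface, "time_weight_grid"))
  asc <- paste0(path, ".asc")
  meta <- paste0(path, ".yaml")
  write_esri_ascii(surface$grid, surface$weights, asc)
  yaml::write_yaml(list(method = surface$method,
                        bandwidth_or_radius_m = surface$bandwidth_or_radius,
                        cell_size_m = surface$grid$cell_size), meta)
  invisible(c(asc, meta))
}
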