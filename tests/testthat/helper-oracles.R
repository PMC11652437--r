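# Independently coded brute-force oracles and small fixtures. These are
# deliberately naive (double loops, closed forms) and share no code with
# the implementations they check.

# Quartic-kernel accumulation, one epoch at a time, double loop over cells.
bf_kde_weights <- function(track, grid, bandwidth) {
  s <- grid$cell_size
  w <- matrix(0, grid$nrows, grid$ncols)
  for (e in seq_len(nrow(track))) {
    k <- matrix(0, grid$nrows, grid$ncols)
    for (r in seq_len(grid$nrows)) {
      for (c in seq_len(grid$ncols)) {
        cx <- grid$origin_x + (c - 0.5) * s
        cy <- grid$origin_y + (r - 0.5) * s
        d2 <- (track$x[e] - cx)^2 + (track$y[e] - cy)^2
        if (d2 < bandwidth^2) k[r, c] <- (1 - d2 / bandwidth^2)^2
      }
    }
    w <- w + k / sum(k)
  }
  w / sum(w)
}

# Point-in-capsule test per cell center over the whole grid.
bf_path_covered <- function(track, grid, radius, gap_break_min = 5) {
  s <- grid$cell_size
  piece <- c(0, cumsum(diff(track$t) > gap_break_min * 60))
  covered <- matrix(FALSE, grid$nrows, grid$ncols)
  for (r in seq_len(grid$nrows)) {
    for (c in seq_len(grid$ncols)) {
      cx <- grid$origin_x + (c - 0.5) * s
      cy <- grid$origin_y + (r - 0.5) * s
      for (p in unique(piece)) {
        seg <- track[piece == p, , drop = FALSE]
        if (nrow(seg) == 1) {
          if ((cx - seg$x)^2 + (cy - seg$y)^2 <= radius^2) {
            covered[r, c] <- TRUE
          }
        } else {
          for (i in seq_len(nrow(seg) - 1)) {
            ax <- seg$x[i]; ay <- seg$y[i]
            bx <- seg$x[i + 1]; by <- seg$y[i + 1]
            dx <- bx - ax; dy <- by - ay
            l2 <- dx^2 + dy^2
            tt <- if (l2 == 0) 0 else
              min(1, max(0, ((cx - ax) * dx + (cy - ay) * dy) / l2))
            if ((cx - ax - tt * dx)^2 + (cy - ay - tt * dy)^2 <= radius^2) {
              covered[r, c] <- TRUE
            }
          }
        }
        if (covered[r, c]) break
      }
    }
  }
  covered
}

# Bellman-Ford style dynamic programming on the lattice node grid.
bf_lattice_distances <- function(extent, block, src_ix, src_iy) {
  k <- extent / block
  d <- matrix(Inf, k + 1, k + 1)  # [ix+1, iy+1]
  d[src_ix + 1, src_iy + 1] <- 0
  repeat {
    changed <- FALSE
    for (ix in 0:k) for (iy in 0:k) {
      best <- d[ix + 1, iy + 1]
      if (ix > 0) best <- min(best, d[ix, iy + 1] + block)
      if (ix < k) best <- min(best, d[ix + 2, iy + 1] + block)
      if (iy > 0) best <- min(best, d[ix + 1, iy] + block)
      if (iy < k) best <- min(best, d[ix + 1, iy + 2] + block)
      if (best < d[ix + 1, iy + 1]) {
        d[ix + 1, iy + 1] <- best
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  d
}

# Length-weighted greenspace mean per cell, double loop.
bf_greenspace <- function(segs, grid, buffer = 25, weight_radius = 50) {
  s <- grid$cell_size
  vals <- matrix(NA_real_, grid$nrows, grid$ncols)
  seg_dist <- function(px, py, ax, ay, bx, by) {
    dx <- bx - ax; dy <- by - ay; l2 <- dx^2 + dy^2
    tt <- if (l2 == 0) 0 else
      min(1, max(0, ((px - ax) * dx + (py - ay) * dy) / l2))
    sqrt((px - ax - tt * dx)^2 + (py - ay - tt * dy)^2)
  }
  chord <- function(px, py, ax, ay, bx, by, R) {
    # numeric integration-free closed form via the quadratic roots
    dx <- bx - ax; dy <- by - ay
    a <- dx^2 + dy^2
    if (a == 0) return(0)
    b <- 2 * ((ax - px) * dx + (ay - py) * dy)
    cc <- (ax - px)^2 + (ay - py)^2 - R^2
    disc <- b^2 - 4 * a * cc
    if (disc <= 0) return(0)
    t0 <- max(0, (-b - sqrt(disc)) / (2 * a))
    t1 <- min(1, (-b + sqrt(disc)) / (2 * a))
    max(0, t1 - t0) * sqrt(a)
  }
  for (r in seq_len(grid$nrows)) {
    for (c in seq_len(grid$ncols)) {
      px <- grid$origin_x + (c - 0.5) * s
      py <- grid$origin_y + (r - 0.5) * s
      num <- 0; den <- 0
      for (i in seq_len(nrow(segs))) {
        if (seg_dist(px, py, segs$x0[i], segs$y0[i],
                     segs$x1[i], segs$y1[i]) <= buffer) {
          wl <- chord(px, py, segs$x0[i], segs$y0[i], segs$x1[i],
                      segs$y1[i], weight_radius)
          num <- num + wl * segs$green_pct[i]
          den <- den + wl
        }
      }
      if (den > 0) vals[r, c] <- num / den
    }
  }
  vals
}

bf_weighted_sum <- function(w, v) {
  acc <- 0; wd <- 0
  for (r in seq_len(nrow(w))) {
    for (c in seq_len(ncol(w))) {
      if (!is.na(v[r, c])) {
        acc <- acc + w[r, c] * v[r, c]
        wd <- wd + w[r, c]
      }
    }
  }
  acc / wd
}

# Small fixtures ------------------------------------------------------------

tiny_config <- function(seed = 1, ...) {
  synthetic_config(n_participants = 3, region_extent = 2000,
                   tract_size = 500, seed = seed, ...)
}

make_track <- function(t, x, y, ...) gps_track(t, x, y, ...)

# uniform weights over a set of cells
uniform_surface <- function(grid, cells_idx, method = "kde", param = 250) {
  w <- matrix(0, grid$nrows, grid$ncols)
  w[cells_idx] <- 1 / length(cells_idx)
  time_weight_grid(grid, w, method, param)
}
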