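test_that("a single epoch yields a unit-mass kernel centred on its cell", {
  g <- grid_spec(0, 0, 50, 20, 20)
  tr <- make_track(0, 475, 475)  # a cell center
  s <- kde_surface(tr, g, bandwidth = 250)
  expect_equal(sum(s$weights), 1, tolerance = 1e-12)
  peak <- which(s$weights == max(s$weights), arr.ind = TRUE)
  expect_equal(as.integer(peak), c(10L, 10L))
  # mass containment: nothing farther than the bandwidth from the point
  ctr <- cell_centers(g)
  d <- sqrt(outer((ctr$y - 475)^2, (ctr$x - 475)^2, `+`))
  expect_true(all(s$weights[d >= 250] == 0))
})

test_that("KDE is invariant to duplicating the track in time", {
  g <- grid_spec(0, 0, 50, 20, 20)
  one <- kde_surface(make_track(0, 312, 641), g)
  two <- kde_surface(make_track(c(0, 10), c(312, 312), c(641, 641)), g)
  expect_equal(one$weights, two$weights, tolerance = 1e-12)
})

test_that("KDE matches the brute-force per-point kernel loop", {
  set.seed(23)
  g <- grid_spec(0, 0, 50, 25, 25)
  n <- 100
  tr <- make_track(10 * (0:(n - 1)),
                   runif(n, 300, 950), runif(n, 300, 950))
  fast <- kde_surface(tr, g, bandwidth = 250)
  slow <- bf_kde_weights(as.data.frame(tr), g, 250)
  expect_lt(max(abs(fast$weights - slow)), 1e-9)
})

test_that("KDE is equivariant under joint translation of track and grid", {
  set.seed(29)
  g <- grid_spec(0, 0, 50, 15, 15)
  tr <- make_track(10 * (0:19), runif(20, 250, 500), runif(20, 250, 500))
  s1 <- kde_surface(tr, g)
  shift <- c(1250, -700)
  g2 <- grid_spec(shift[1], shift[2], 50, 15, 15)
  tr2 <- make_track(tr$t, tr$x + shift[1], tr$y + shift[2])
  s2 <- kde_surface(tr2, g2)
  expect_equal(s1$weights, s2$weights, tolerance = 1e-12)
})

test_that("a stationary epoch buffers to a uniform disc", {
  g <- grid_spec(0, 0, 50, 20, 20)
  s <- daily_path_surface(make_track(0, 500, 500), g, radius = 250)
  ctr <- cell_centers(g)
  inside <- outer((ctr$y - 500)^2, (ctr$x - 500)^2, `+`) <= 250^2
  expect_equal(s$weights > 0, inside)
  expect_equal(unique(s$weights[inside]), 1 / sum(inside))
})

test_that("daily path coverage equals the point-in-capsule oracle and is
           monotone in radius", {
  g <- grid_spec(0, 0, 50, 30, 30)
  # straight 1,000-m two-epoch path
  tr <- make_track(c(0, 10), c(250, 1250), c(700, 740))
  s <- daily_path_surface(tr, g, radius = 250)
  oracle <- bf_path_covered(as.data.frame(tr), g, 250)
  expect_equal(s$weights > 0, oracle)
  # a jagged multi-piece track with a >5-min break
  set.seed(31)
  tr2 <- make_track(c(0, 10, 20, 30, 1000, 1010),
                    runif(6, 300, 1200), runif(6, 300, 1200))
  s2 <- daily_path_surface(tr2, g, radius = 180)
  expect_equal(s2$weights > 0, bf_path_covered(as.data.frame(tr2), g, 180))
  # covered area at 250 m contains covered area at 100 m
  s100 <- daily_path_surface(tr, g, radius = 100)
  expect_true(all(s$weights[s100$weights > 0] > 0))
})

test_that("euclidean residential buffers stay within their radius", {
  g <- grid_spec(0, 0, 50, 40, 40)
  home <- c(1000, 1000)
  s <- residential_buffer_surface(home, g, 800, "euclidean")
  ctr <- cell_centers(g)
  d <- sqrt(outer((ctr$y - home[2])^2, (ctr$x - home[1])^2, `+`))
  expect_true(all(d[s$weights > 0] <= 800))
  expect_error(residential_buffer_surface(c(-5000, 0), g, 800, "euclidean"),
               "outside")
  expect_error(residential_buffer_surface(home, g, 800, "network"),
               "street")
})

test_that("lattice shortest paths agree with a dynamic-programming oracle
           and bound the euclidean distance", {
  streets <- street_lattice(1000, 200)
  d <- lattice_node_distances(streets, 410, 390)  # snaps to (400, 400)
  oracle <- bf_lattice_distances(1000, 200, 2, 2)
  for (i in seq_len(nrow(streets$nodes))) {
    ix <- streets$nodes$x[i] / 200
    iy <- streets$nodes$y[i] / 200
    expect_equal(d[i], oracle[ix + 1, iy + 1])
  }
  # nodes within 800 m network distance lie inside the euclidean disc
  home <- c(400, 400)
  eu <- sqrt((streets$nodes$x - home[1])^2 + (streets$nodes$y - home[2])^2)
  expect_true(all(eu[d <= 800] <= 800))
})

test_that("network service areas are tighter than euclidean discs at the
           node level", {
  streets <- street_lattice(2000, 200)
  g <- grid_spec(0, 0, 50, 40, 40)
  home <- c(1000, 1000)
  s_net <- residential_buffer_surface(home, g, 800, "network", streets)
  s_eu <- residential_buffer_surface(home, g, 800 + streets$block,
                                     "euclidean")
  # network coverage buffered by a block is inside the euclidean disc of
  # radius + block
  expect_true(all(s_eu$weights[s_net$weights > 0] > 0))
  expect_equal(sum(s_net$weights), 1, tolerance = 1e-12)
})
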