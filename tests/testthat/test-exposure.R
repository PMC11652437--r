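test_that("the worked two-cell overlay reproduces its arithmetic", {
  g <- grid_spec(0, 0, 50, 1, 2)
  w <- matrix(c(0.12, 0.88), 1, 2)
  surface <- time_weight_grid(g, w, "kde", 250)
  layer <- env_layer(g, matrix(10, 1, 2), "walkability")
  expect_equal(weighted_exposure(surface, layer), 10)
  # the 12%-of-time cell contributes 10 x 0.12 = 1.2 on its own
  lone <- env_layer(g, matrix(c(10, 0), 1, 2), "park_distance_m")
  expect_equal(weighted_exposure(surface, lone), 1.2, tolerance = 1e-12)
})

test_that("exposure to a constant layer is that constant", {
  set.seed(43)
  g <- grid_spec(0, 0, 50, 8, 8)
  w <- matrix(runif(64), 8, 8); w <- w / sum(w)
  surface <- time_weight_grid(g, w, "kde", 250)
  layer <- env_layer(g, matrix(17.5, 8, 8), "walkability")
  expect_equal(weighted_exposure(surface, layer), 17.5, tolerance = 1e-12)
})

test_that("weighted exposure matches an independent double loop and is
           linear in the layer", {
  set.seed(47)
  g <- grid_spec(0, 0, 50, 20, 20)
  w <- matrix(rexp(400), 20, 20); w <- w / sum(w)
  v <- matrix(runif(400, 0, 100), 20, 20)
  v[sample(400, 30)] <- NA
  surface <- time_weight_grid(g, w, "kde", 250)
  layer <- env_layer(g, v, "green_pct")
  expect_equal(weighted_exposure(surface, layer), bf_weighted_sum(w, v),
               tolerance = 1e-12)
  # linearity: a*v1 + b*v2 (on fully defined layers)
  v1 <- matrix(runif(400, 0, 50), 20, 20)
  v2 <- matrix(runif(400, 0, 50), 20, 20)
  e1 <- weighted_exposure(surface, env_layer(g, v1, "green_pct"))
  e2 <- weighted_exposure(surface, env_layer(g, v2, "green_pct"))
  e12 <- weighted_exposure(surface,
                           env_layer(g, 0.3 * v1 + 0.7 * v2, "green_pct"))
  expect_equal(e12, 0.3 * e1 + 0.7 * e2, tolerance = 1e-9)
  # bounds: a convex combination of layer values over positive-weight cells
  expect_gte(weighted_exposure(surface, layer), min(v[w > 0], na.rm = TRUE))
  expect_lte(weighted_exposure(surface, layer), max(v[w > 0], na.rm = TRUE))
})

test_that("nodata handling renormalizes by default and can zero-fill", {
  g <- grid_spec(0, 0, 50, 1, 3)
  surface <- time_weight_grid(g, matrix(c(0.5, 0.3, 0.2), 1), "kde", 250)
  v <- matrix(c(10, NA, 20), 1)
  layer <- env_layer(g, v, "green_pct")
  expect_equal(weighted_exposure(surface, layer),
               (0.5 * 10 + 0.2 * 20) / 0.7)
  expect_equal(weighted_exposure(surface, layer, nodata_policy = "zero"),
               0.5 * 10 + 0.2 * 20)
  all_na <- env_layer(g, matrix(NA_real_, 1, 3), "green_pct")
  expect_warning(res <- weighted_exposure(surface, all_na), "nodata")
  expect_true(is.na(res))
  g2 <- grid_spec(0, 0, 50, 1, 2)
  expect_error(weighted_exposure(surface,
                                 env_layer(g2, matrix(1, 1, 2),
                                           "green_pct")),
               "grid")
})

test_that("any-park exposure is strict positivity of overlap weight", {
  g <- grid_spec(0, 0, 50, 2, 2)
  parks <- env_layer(g, matrix(c(1, 0, 0, 0), 2, 2), "park_indicator")
  off <- time_weight_grid(g, matrix(c(0, 0.5, 0.25, 0.25), 2, 2),
                          "kde", 250)
  expect_false(parks_any_exposure(off, parks))
  tiny <- time_weight_grid(g, matrix(c(1e-6, 1 - 1e-6, 0, 0), 2, 2),
                           "kde", 250)
  expect_true(parks_any_exposure(tiny, parks))
  # equivalence with a strictly positive weighted indicator exposure
  set.seed(53)
  for (i in 1:25) {
    w <- matrix(rbinom(4, 1, 0.4) * runif(4), 2, 2)
    if (sum(w) == 0) w[1] <- 1
    s <- time_weight_grid(g, w / sum(w), "kde", 250)
    expect_identical(parks_any_exposure(s, parks),
                     weighted_exposure(s, parks, "zero") > 0)
  }
})

test_that("a stationary park day reads the layers underneath it", {
  cfg <- tiny_config(seed = 5)
  env <- generate_environment(cfg)
  p <- env$parks[1, ]
  cx <- (p$xmin + p$xmax) / 2; cy <- (p$ymin + p$ymax) / 2
  n <- 2200  # > 6 h
  tr <- gps_track(10 * (0:(n - 1)), rep(cx, n), rep(cy, n),
                  participant_id = "P001", wave = "T1",
                  date = "2017-03-06", day_type = "weekday")
  rec <- derive_day_exposures(tr, env, method = "kde", bandwidth = 100)
  expect_equal(rec$parks_any, 1L)
  # walkability of a stationary day is (close to) the local tract score
  tract <- env$tracts[cx >= env$tracts$xmin & cx < env$tracts$xmax &
                        cy >= env$tracts$ymin & cy < env$tracts$ymax, ]
  expect_lt(abs(rec$walkability - tract$score), 1.5)
  rec2 <- derive_day_exposures(tr, env, method = "daily_path", radius = 100)
  expect_equal(rec2$method, "daily_path")
  expect_equal(rec$method, "kde")
})

test_that("full-day exposure metrics agree with a composition of the
           component oracles", {
  cfg <- tiny_config(seed = 9)
  env <- generate_environment(cfg)
  roster <- generate_participant_roster(cfg)
  tr <- generate_gps_day(roster[1, ], "T1", "2017-03-06", "weekday", env,
                         cfg, seed = 99)
  full <- attr(tr, "full_track")
  rec <- derive_day_exposures(full, env, method = "kde", bandwidth = 250)
  w <- kde_surface(full, env$grid, 250)$weights
  expect_equal(rec$green_pct,
               bf_weighted_sum(w, env$greenspace_layer$values),
               tolerance = 1e-9)
  expect_equal(rec$walkability,
               bf_weighted_sum(w, env$walkability_layer$values),
               tolerance = 1e-9)
  expect_equal(rec$park_distance_m,
               bf_weighted_sum(w, env$park_distance_layer$values),
               tolerance = 1e-9)
  expect_identical(rec$parks_any,
                   as.integer(any(w > 0 & env$parks_layer$values == 1)))
})
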