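test_that("environment generation is deterministic and respects ranges", {
  cfg <- tiny_config(seed = 1)
  e1 <- generate_environment(cfg)
  e2 <- generate_environment(cfg)
  expect_identical(e1$greenspace_layer$values, e2$greenspace_layer$values)
  expect_identical(e1$walkability_layer$values, e2$walkability_layer$values)
  expect_identical(e1$parks, e2$parks)
  w <- e1$walkability_layer$values
  expect_true(all(w[!is.na(w)] >= 1 & w[!is.na(w)] <= 20))
  g <- e1$greenspace_layer$values
  expect_true(all(g[!is.na(g)] >= 0 & g[!is.na(g)] <= 100))
  expect_true(all(e1$park_distance_layer$values >= 0))
  expect_error(generate_environment(tiny_config(n_parks = 0)), "park")
  expect_error(generate_environment(
    synthetic_config(region_extent = 200, cell_size = 50, block_size = 200,
                     seed = 1)), "small")
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(n_participants = 1), "at least 2")
  expect_error(synthetic_config(days_per_wave = 1), "at least 2")
  expect_error(synthetic_config(region_extent = 1025), "multiple")
  expect_error(effect_truth(within_park_effect = 0), "positive")
  expect_error(effect_truth(between_sd = -1), "positive")
})

test_that("the roster is reproducible, eligible, and matches its sampler", {
  cfg <- synthetic_config(n_participants = 55, seed = 3)
  r1 <- generate_participant_roster(cfg)
  r2 <- generate_participant_roster(cfg)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 55)
  expect_true(all(r1$age >= 18))
  expect_true(all(r1$deprivation %in% 1:10))
  expect_true(all(r1$cohesion_safety >= 1 & r1$cohesion_safety <= 5))
  expect_true(all(r1$home_x %% cfg$block_size == 0))
})

test_that("large-n roster moments match the truncated-normal closed form", {
  # independent oracle: moments of N(29, 6.1) truncated at 18
  alpha <- (18 - 29) / 6.1
  lambda <- dnorm(alpha) / (1 - pnorm(alpha))
  mu_trunc <- 29 + 6.1 * lambda
  sd_trunc <- 6.1 * sqrt(1 + alpha * lambda - lambda^2)
  cfg <- synthetic_config(n_participants = 10000, seed = 5)
  r <- generate_participant_roster(cfg)
  expect_lt(abs(mean(r$age) - mu_trunc), 0.2)
  expect_lt(abs(sd(r$age) - sd_trunc), 0.2)
  expect_lt(abs(mean(r$education == "some_college_plus") - 0.3455), 0.02)
  expect_lt(abs(mean(r$parity == "first_born") - 0.2909), 0.02)
  expect_lt(abs(mean(r$bmi_category == "obese") - 0.382), 0.02)
})

test_that("a clean GPS day stays in the region on an exact 10-s lattice", {
  cfg <- tiny_config(seed = 7, park_visit_prob = 0,
                     gps_dropout_prob = 0, gps_severe_prob = 0)
  env <- generate_environment(cfg)
  r <- generate_participant_roster(cfg)
  tr <- generate_gps_day(r[1, ], "T1", "2017-03-06", "weekday", env, cfg,
                         seed = 21)
  expect_equal(nrow(tr), cfg$waking_hours * 360)
  expect_true(all(diff(tr$t) == 10))
  expect_true(all(tr$x >= 0 & tr$x <= cfg$region_extent))
  expect_true(all(tr$y >= 0 & tr$y <= cfg$region_extent))
  expect_error(generate_gps_day(r[1, ], "T1", "2017-03-06", "weekday",
                                env, cfg, seed = NA), "seed")
})

test_that("severe GPS deletion pushes a day below the 6-h validity floor", {
  cfg <- tiny_config(seed = 7, gps_severe_prob = 1, gps_dropout_prob = 0)
  env <- generate_environment(cfg)
  r <- generate_participant_roster(cfg)
  tr <- generate_gps_day(r[2, ], "T3", "2017-09-04", "weekday", env, cfg,
                         seed = 22)
  imputed <- impute_gaps(tr)
  expect_false(gps_day_valid(imputed)$valid)
})

test_that("park-visit days without jitter put epochs inside a park", {
  cfg <- tiny_config(seed = 7, park_visit_prob = 1, jitter_sd = 0,
                     gps_dropout_prob = 0, gps_severe_prob = 0)
  env <- generate_environment(cfg)
  r <- generate_participant_roster(cfg)
  tr <- generate_gps_day(r[1, ], "T1", "2017-03-06", "weekday", env, cfg,
                         seed = 23)
  in_park <- rep(FALSE, nrow(tr))
  for (i in seq_len(nrow(env$parks))) {
    in_park <- in_park |
      (tr$x >= env$parks$xmin[i] & tr$x < env$parks$xmax[i] &
         tr$y >= env$parks$ymin[i] & tr$y < env$parks$ymax[i])
  }
  expect_true(any(in_park))
})

test_that("the noise-free accelerometer limit realizes the baseline", {
  cfg <- tiny_config(seed = 7, accel_nonwear_prob = 0,
                     accel_lowwear_prob = 0, gps_dropout_prob = 0,
                     gps_severe_prob = 0,
                     truth = effect_truth(within_park_effect = 1,
                                          within_walkability_effect = 1,
                                          within_sd = 1e-9))
  env <- generate_environment(cfg)
  r <- generate_participant_roster(cfg)
  for (s in 31:33) {
    tr <- generate_gps_day(r[1, ], "T1", "2017-03-06", "weekday", env, cfg,
                           seed = s)
    acc <- generate_accel_day(tr, cfg$truth, env, cfg, person_effect = 0,
                              seed = s + 100)
    realized <- day_mvpa_minutes(epoch_mvpa_mask(acc))
    expect_lt(abs(realized - exp(3.0)), 1 / 6 + 1e-6)
  }
})

test_that("injected non-wear blocks trip the non-wear detector", {
  cfg <- tiny_config(seed = 7, accel_nonwear_prob = 1,
                     accel_lowwear_prob = 0, gps_dropout_prob = 0,
                     gps_severe_prob = 0)
  env <- generate_environment(cfg)
  r <- generate_participant_roster(cfg)
  tr <- generate_gps_day(r[1, ], "T1", "2017-03-06", "weekday", env, cfg,
                         seed = 41)
  acc <- generate_accel_day(tr, cfg$truth, env, cfg, seed = 42)
  expect_true(attr(acc, "truth")$degraded)
  wear <- detect_nonwear(acc)
  expect_gt(sum(!wear), 360)  # the injected >60-min block is non-wear
})

test_that("the panel-level simulator recovers the injected park contrast
           by brute force on the truth labels", {
  truth <- effect_truth(within_park_effect = 1.25)
  panel <- simulate_analysis_panel(n_participants = 50,
                                   days_per_person = 10,
                                   truth = truth, seed = 61)
  expect_equal(nrow(panel), 500)
  # within-person log contrast, averaged over persons with both day types
  lg <- log(panel$mvpa_minutes)
  contrasts <- vapply(split(seq_len(500), panel$participant_id),
                      function(i) {
    p <- panel$parks_any[i]
    if (all(p == 1) || all(p == 0)) return(NA_real_)
    mean(lg[i][p == 1]) - mean(lg[i][p == 0])
  }, numeric(1))
  est <- exp(mean(contrasts, na.rm = TRUE))
  expect_lt(abs(log(est) - log(1.25)), 2.5 * 0.66 * sqrt(4 / 500))
})

test_that("a generated study has the configured day count, reproduces
           byte-identically, and round-trips MVPA truth", {
  cfg <- synthetic_config(n_participants = 2, days_per_wave = 2,
                          region_extent = 2000, tract_size = 500, seed = 13)
  d1 <- file.path(tempdir(), "study_a")
  d2 <- file.path(tempdir(), "study_b")
  unlink(c(d1, d2), recursive = TRUE)
  s1 <- generate_study(cfg, d1)
  s2 <- generate_study(cfg, d2)
  n_days <- cfg$n_participants * length(cfg$waves) * cfg$days_per_wave
  expect_equal(nrow(s1$truth), n_days)
  expect_equal(length(list.files(file.path(d1, "gps"))), n_days)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f1))
  expect_true(all(unname(h1) == unname(h2)))
  # pipeline recomputation of MVPA equals generator truth on clean days
  act <- process_accel_days(d1)
  merged <- merge(act, s1$truth, by = c("participant_id", "wave", "date"))
  clean <- merged[!merged$accel_degraded, ]
  expect_gt(nrow(clean), 0)
  expect_true(all(abs(clean$mvpa_minutes.x - clean$mvpa_minutes.y)
                  <= 1 / 6 + 1e-9))
  # daily temperatures centre on the configured climate
  expect_true(all(is.finite(s1$temperature$temp_c)))
  unlink(c(d1, d2), recursive = TRUE)
})
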