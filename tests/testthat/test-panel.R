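mk_expo <- function(pid, wave, date, gps_valid = TRUE) {
  data.frame(participant_id = pid, wave = wave, date = date,
             day_type = "weekday", method = "kde", param_m = 250,
             gps_valid = gps_valid, coverage_hours = 10,
             green_pct = 25, park_distance_m = 500, parks_any = 1L,
             walkability = 15, stringsAsFactors = FALSE)
}
mk_act <- function(pid, wave, date, accel_valid = TRUE) {
  data.frame(participant_id = pid, wave = wave, date = date,
             wear_hours = 12, accel_valid = accel_valid,
             mvpa_minutes = 30, stringsAsFactors = FALSE)
}
mk_roster <- function(pids) {
  data.frame(participant_id = pids, age = 29,
             education = "high_school_or_less",
             parity = "second_or_greater", bmi_category = "normal",
             employed = 0L, deprivation = 6, cohesion_safety = 3,
             home_x = 200, home_y = 200, stringsAsFactors = FALSE)
}

test_that("panel assembly drops days failing either validity rule", {
  expo <- rbind(mk_expo("P1", "T1", "d1"),
                mk_expo("P1", "T1", "d2", gps_valid = FALSE),
                mk_expo("P1", "T1", "d3"),
                mk_expo("P2", "T1", "d1"))
  act <- rbind(mk_act("P1", "T1", "d1"),
               mk_act("P1", "T1", "d2"),
               mk_act("P1", "T1", "d3", accel_valid = FALSE),
               mk_act("P2", "T1", "d1"),
               mk_act("P2", "T1", "d9"))  # no exposure match
  p <- assemble_panel(expo, act, mk_roster(c("P1", "P2")), quiet = TRUE)
  expect_equal(nrow(p), 2)
  excl <- attr(p, "exclusions")
  expect_equal(unname(excl["accel_days"]), 5)
  expect_equal(unname(excl["matched"]), 4)
  expect_equal(unname(excl["removed_accel_invalid"]), 1)
  expect_equal(unname(excl["removed_gps_invalid"]), 1)
  expect_equal(unname(excl["final"]), 2)
  expect_true(all(c("park_distance_100m", "weekend") %in% names(p)))
  expect_error(assemble_panel(rbind(expo, expo[1, ]), act,
                              mk_roster(c("P1", "P2")), quiet = TRUE),
               "duplicate")
})

test_that("retained-row counts match a brute-force recount on a generated
           study", {
  cfg <- synthetic_config(n_participants = 3, days_per_wave = 2,
                          region_extent = 2000, tract_size = 500, seed = 19)
  dir <- file.path(tempdir(), "study_recount")
  unlink(dir, recursive = TRUE)
  st <- generate_study(cfg, dir)
  expo <- process_gps_days(dir, st$env)
  act <- process_accel_days(dir)
  p <- assemble_panel(expo, act, st$roster, st$temperature, quiet = TRUE)
  ok_gps <- expo[expo$gps_valid, c("participant_id", "wave", "date")]
  ok_acc <- act[act$accel_valid, c("participant_id", "wave", "date")]
  expect_equal(nrow(p), nrow(merge(ok_gps, ok_acc)))
  unlink(dir, recursive = TRUE)
})

test_that("the outcome transform is exact at its anchors and invertible", {
  expect_equal(transform_outcome(0), 0)
  expect_equal(transform_outcome(exp(1) - 1), 1)
  x <- c(0, 0.5, 10, 123.4)
  expect_equal(back_transform_outcome(transform_outcome(x)), x,
               tolerance = 1e-12)
  expect_error(transform_outcome(-1), "non-negative")
})

test_that("person-mean centering decomposes exactly", {
  panel <- data.frame(
    participant_id = rep(c("A", "B"), each = 3),
    green_pct = c(9, 10, 11, 19, 20, 21),
    park_distance_100m = c(5, 5, 5, 7, 8, 9),
    walkability = c(14, 15, 16, 15, 15, 15),
    parks_any = c(1L, 0L, 1L, 0L, 0L, 1L))
  out <- person_mean_center(panel)
  # two persons with means 10 and 20: BS terms -5 and +5
  expect_equal(unique(out$green_pct_bs), c(-5, 5))
  # constant within person: WS identically zero
  expect_equal(out$walkability_ws[4:6], rep(0, 3))
  # WS sums to zero within person for continuous metrics
  for (v in c("green_pct_ws", "park_distance_100m_ws", "walkability_ws")) {
    expect_equal(as.numeric(tapply(out[[v]], out$participant_id, sum)),
                 c(0, 0), tolerance = 1e-12)
  }
  # exact reconstruction: grand mean + BS + WS
  grand <- mean(tapply(panel$green_pct, panel$participant_id, mean))
  expect_equal(grand + out$green_pct_bs + out$green_pct_ws,
               panel$green_pct, tolerance = 1e-12)
  # binary: BS is the centred person proportion, WS the raw indicator
  expect_equal(out$parks_any_ws, panel$parks_any)
  expect_equal(unique(round(out$parks_any_bs, 10)),
               round(c(2 / 3, 1 / 3) - 0.5, 10))
  cent <- person_mean_center(panel, center_binary = TRUE)
  expect_equal(as.numeric(tapply(cent$parks_any_ws, cent$participant_id, sum)),
               c(0, 0), tolerance = 1e-12)
  expect_error(person_mean_center(panel, variables = "nope"), "nope")
})
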