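# Balanced one-way random-effects data for closed-form checks.
balanced_panel <- function(n, k, sd_b, sd_w, seed, mu = 3) {
  set.seed(seed)
  b <- rnorm(n, 0, sd_b)
  data.frame(
    participant_id = rep(sprintf("P%02d", 1:n), each = k),
    log_mvpa = mu + rep(b, each = k) + rnorm(n * k, 0, sd_w))
}

test_that("the null ICC model matches closed-form ANOVA estimators on
           balanced data", {
  n <- 30; k <- 6
  panel <- balanced_panel(n, k, sd_b = 0.6, sd_w = 0.7, seed = 71)
  res <- fit_null_icc(panel)
  # one-way ANOVA variance components (REML = ANOVA for balanced designs)
  pm <- tapply(panel$log_mvpa, panel$participant_id, mean)
  msb <- k * var(pm)
  msw <- sum((panel$log_mvpa - rep(pm, each = k))^2) / (n * (k - 1))
  sigma_b2 <- (msb - msw) / k
  expect_equal(res$within_var, msw, tolerance = 1e-6)
  expect_equal(res$between_var, sigma_b2, tolerance = 1e-6)
  expect_equal(res$icc, sigma_b2 / (sigma_b2 + msw), tolerance = 1e-6)
  expect_true(res$icc >= 0 && res$icc <= 1)
})

test_that("zero between-person variance yields a near-zero ICC", {
  panel <- balanced_panel(150, 8, sd_b = 1e-12, sd_w = 0.7, seed = 73)
  # a boundary (singular) fit is expected and reported, not hidden
  res <- suppressWarnings(fit_null_icc(panel))
  expect_lte(res$icc, 0.05)
  expect_error(fit_null_icc(balanced_panel(1, 5, 0.5, 0.5, 1)),
               "two participants")
})

test_that("main-model estimates are invariant to covariate shifts and row
           order", {
  panel <- simulate_analysis_panel(n_participants = 25, days_per_person = 6,
                                   seed = 79)
  fit1 <- fit_main_model(panel)
  shifted <- panel
  shifted$age <- shifted$age + 10
  fit2 <- fit_main_model(shifted)
  keep <- setdiff(fit1$tidy$term, "(Intercept)")
  expect_equal(fit1$tidy$estimate_log[fit1$tidy$term %in% keep],
               fit2$tidy$estimate_log[fit2$tidy$term %in% keep],
               tolerance = 1e-6)
  # row order / relabeling invariance
  perm <- panel[sample(nrow(panel)), ]
  fit3 <- fit_main_model(perm)
  expect_equal(fit1$tidy$estimate_log, fit3$tidy$estimate_log,
               tolerance = 1e-6)
  # CI bounds bracket the exponentiated estimate
  expect_true(all(fit1$tidy$ci_low <= fit1$tidy$estimate_exp &
                    fit1$tidy$estimate_exp <= fit1$tidy$ci_high))
})

test_that("rank-deficient designs fail loudly with the aliased columns", {
  panel <- simulate_analysis_panel(n_participants = 20, days_per_person = 5,
                                   seed = 83)
  panel$dup <- panel$green_pct_dup <- panel$green_pct
  p <- person_mean_center(panel)
  p$log_mvpa <- transform_outcome(p$mvpa_minutes)
  expect_error(
    fit_main_model(p, exposures = c(default_exposure_terms(), "dup",
                                    "green_pct_dup"),
                   covariates = c("temp_c", "weekend")),
    "aliased")
})

test_that("interaction models obey the binary-modifier coding identity and
           centering invariance", {
  panel <- simulate_analysis_panel(n_participants = 30, days_per_person = 8,
                                   seed = 89)
  fit <- fit_interaction_model(panel, "walkability_ws", "employed",
                               covariates = c("age", "temp_c", "weekend",
                                              "wave", "wear_hours",
                                              "employed"))
  b <- lme4::fixef(fit$fit)
  ss <- simple_slopes(fit, levels = c(ref = 0, employed = 1))
  # at modifier 0 the simple slope is the exposure main effect
  expect_equal(ss$slope_log[1], unname(b[["walkability_ws"]]),
               tolerance = 1e-10)
  expect_equal(ss$slope_log[2],
               unname(b[["walkability_ws"]] +
                        b[["walkability_ws:employed"]]),
               tolerance = 1e-10)
  # centering the modifier shifts main effects, not the interaction term
  panel2 <- panel
  panel2$employed <- panel2$employed - mean(panel2$employed)
  fit2 <- fit_interaction_model(panel2, "walkability_ws", "employed",
                                covariates = c("age", "temp_c", "weekend",
                                               "wave", "wear_hours",
                                               "employed"))
  expect_equal(lme4::fixef(fit2$fit)[["walkability_ws:employed"]],
               b[["walkability_ws:employed"]], tolerance = 1e-6)
  expect_error(fit_interaction_model(transform(panel, const = 1),
                                     "walkability_ws", "const"),
               "constant")
})

test_that("delta-method simple slopes agree with a refit at a shifted
           modifier, and are symmetric about the mean", {
  panel <- simulate_analysis_panel(n_participants = 30, days_per_person = 8,
                                   seed = 97)
  covs <- c("age", "temp_c", "weekend", "wave", "wear_hours")
  fit <- fit_interaction_model(panel, "parks_any_ws", "cohesion_safety",
                               covariates = covs)
  ss <- simple_slopes(fit)
  m <- mean(panel$cohesion_safety)
  # reparameterization oracle: shift the modifier so level m becomes 0
  shifted <- panel
  shifted$cohesion_safety <- shifted$cohesion_safety - m
  refit <- fit_interaction_model(shifted, "parks_any_ws",
                                 "cohesion_safety", covariates = covs)
  row <- refit$tidy[refit$tidy$term == "parks_any_ws", ]
  expect_equal(ss$slope_log[ss$level == "mean"], row$estimate_log,
               tolerance = 1e-6)
  expect_equal(ss$se[ss$level == "mean"], row$se, tolerance = 1e-6)
  # linearity: slopes at +/-1 SD are symmetric about the mean-level slope
  expect_equal(ss$slope_log[1] + ss$slope_log[3], 2 * ss$slope_log[2],
               tolerance = 1e-10)
})

test_that("predicted trajectories are linear in the exposure and finite in
           minutes", {
  panel <- simulate_analysis_panel(n_participants = 25, days_per_person = 6,
                                   seed = 101)
  fit <- fit_interaction_model(panel, "walkability_ws", "bmi_category",
                               covariates = c("age", "temp_c", "weekend",
                                              "wave", "wear_hours",
                                              "bmi_category"))
  tra <- predicted_trajectories(fit, exposure_values = c(-1, 0, 1, 2))
  expect_equal(nrow(tra), 4 * 3)
  # linear in the exposure at fixed modifier level: zero second difference
  for (lev in unique(tra$bmi_category)) {
    y <- tra$pred_log[tra$bmi_category == lev]
    expect_equal(diff(y, differences = 2), rep(0, 2), tolerance = 1e-9)
  }
  expect_true(all(is.finite(tra$pred_minutes)))
  expect_equal(tra$pred_minutes,
               back_transform_outcome(tra$pred_log), tolerance = 1e-12)
})
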