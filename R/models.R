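# Random-intercept mixed models with within/between decomposition, ICC,
# effect modification and simple slopes.

#' Default exposure terms (four metrics, BS and WS)
#' @export
default_exposure_terms <- function() {
  c("green_pct_bs", "park_distance_100m_bs", "walkability_bs",
    "parks_any_bs",
    "green_pct_ws", "park_distance_100m_ws", "walkability_ws",
    "parks_any_ws")
}

#' Default covariate roster
#' @export
default_covariates <- function() {
  c("age", "education", "parity", "bmi_category", "employed", "temp_c",
    "weekend", "wave", "cohesion_safety", "deprivation", "wear_hours")
}

# Coerce categorical covariates to factors with the study's reference
# levels (first trimester, high school or less, second-or-greater birth,
# normal BMI) and add the log outcome if absent.
#' @keywords internal
prepare_model_frame <- function(panel) {
  if (!"log_mvpa" %in% names(panel)) {
    panel$log_mvpa <- transform_outcome(panel$mvpa_minutes)
  }
  relevel_if <- function(col, levels) {
    if (col %in% names(panel) && !is.factor(panel[[col]])) {
      panel[[col]] <<- factor(panel[[col]],
                              levels = intersect(levels,
                                                 unique(panel[[col]])))
    }
  }
  relevel_if("wave", c("T1", "T3", "PP"))
  relevel_if("education", c("high_school_or_less", "some_college_plus"))
  relevel_if("parity", c("second_or_greater", "first_born"))
  relevel_if("bmi_category", c("normal", "overweight", "obese"))
  panel
}

#' @keywords internal
check_rank <- function(formula, data) {
  mm <- stats::model.matrix(formula, data)
  q <- qr(mm)
  if (q$rank < ncol(mm)) {
    aliased <- colnames(mm)[q$pivot[(q$rank + 1):ncol(mm)]]
    stop("rank-deficient fixed-effects design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  invisible(TRUE)
}

#' @keywords internal
lmm_fit <- function(panel, rhs_terms, reml) {
  panel <- prepare_model_frame(panel)
  miss <- setdiff(all.vars(stats::reformulate(rhs_terms)), names(panel))
  if (length(miss)) stop("variables absent from panel: ",
                         paste(miss, collapse = ", "))
  fixed <- stats::reformulate(rhs_terms, response = "log_mvpa")
  check_rank(stats::reformulate(rhs_terms), panel)
  full <- stats::as.formula(paste("log_mvpa ~",
                                  paste(rhs_terms, collapse = " + "),
                                  "+ (1 | participant_id)"))
  fit <- lme4::lmer(full, data = panel, REML = reml)
  msgs <- fit@optinfo$conv$lme4$messages
  list(fit = fit, panel = panel, converged = is.null(msgs),
       messages = msgs, fixed = fixed)
}

#' @keywords internal
variance_components <- function(fit) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  between <- vc$vcov[vc$grp == "participant_id"][1]
  within <- vc$vcov[vc$grp == "Residual"][1]
  list(between_var = between, within_var = within,
       icc = between / (between + within))
}

#' @keywords internal
tidy_fixed <- function(fit, level = 0.95) {
  b <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- b / se
  q <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(
    term = names(b), estimate_log = as.numeric(b), se = as.numeric(se),
    estimate_exp = exp(as.numeric(b)),
    ci_low = exp(as.numeric(b) - q * se),
    ci_high = exp(as.numeric(b) + q * se),
    p = 2 * stats::pnorm(-abs(as.numeric(z))),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Null-model intraclass correlation
#'
#' Fits a random-intercept-only model on the log outcome by restricted
#' maximum likelihood and returns the variance components and
#' `ICC = between / (between + within)`.
#'
#' @param panel Panel data.frame with `participant_id` and either
#'   `log_mvpa` or `mvpa_minutes`.
#' @return List: `between_var`, `within_var`, `icc`, `converged`.
#' @export
fit_null_icc <- function(panel) {
  counts <- table(panel$participant_id)
  if (length(counts) < 2 || sum(counts >= 2) < 2) {
    stop("need at least two participants with at least two days each")
  }
  res <- lmm_fit(panel, "1", reml = TRUE)
  if (!res$converged) {
    warning("null model did not converge cleanly: ",
            paste(res$messages, collapse = "; "))
  }
  c(variance_components(res$fit), list(converged = res$converged))
}

#' Fit the main within/between exposure model
#'
#' Linear mixed model of log MVPA minutes on all four exposure metrics
#' (between- and within-subject terms in the same model) plus the covariate
#' roster, with a random intercept per participant. Estimates are Wald z
#' intervals on the log scale, exponentiated for reporting on the
#' multiplicative scale.
#'
#' @param panel Panel with BS/WS columns (see [person_mean_center()]).
#' @param exposures Character vector of exposure terms.
#' @param covariates Character vector of covariate terms.
#' @param method `"ML"` (default) or `"REML"`.
#' @return A `model_result`: `tidy` (term, log and exponentiated estimates,
#'   95% CI, p), `varcomp`, `converged`, `n_obs`, `n_participants`, and the
#'   underlying `fit`.
#' @export
fit_main_model <- function(panel, exposures = default_exposure_terms(),
                           covariates = default_covariates(),
                           method = c("ML", "REML")) {
  method <- match.arg(method)
  res <- lmm_fit(panel, c(exposures, covariates), reml = method == "REML")
  structure(list(
    tidy = tidy_fixed(res$fit),
    varcomp = variance_components(res$fit),
    converged = res$converged, messages = res$messages,
    n_obs = nrow(res$panel),
    n_participants = length(unique(res$panel$participant_id)),
    method = method, fit = res$fit, data = res$panel,
    terms = c(exposures, covariates)), class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("<model_result> %d rows, %d participants, %s%s\n",
              x$n_obs, x$n_participants, x$method,
              if (x$converged) "" else " (convergence messages)"))
  print(format(x$tidy[, c("term", "estimate_exp", "ci_low", "ci_high", "p")],
               digits = 3), row.names = FALSE)
  cat(sprintf("ICC %.3f (between %.3f, within %.3f)\n",
              x$varcomp$icc, x$varcomp$between_var, x$varcomp$within_var))
  invisible(x)
}

#' Fit an effect-modification model
#'
#' The main model plus a multiplicative interaction between one exposure
#' term and a modifier (categorical or continuous). Interaction p-values
#' are reported at the conventional 0.05 screen with no multiplicity
#' correction.
#'
#' @param panel Panel with BS/WS columns.
#' @param exposure One exposure term, e.g. `"walkability_ws"`.
#' @param modifier A panel column name.
#' @param exposures,covariates As in [fit_main_model()].
#' @param method `"ML"` or `"REML"`.
#' @return A `model_result` whose `tidy` includes the interaction term(s).
#' @export
fit_interaction_model <- function(panel, exposure, modifier,
                                  exposures = default_exposure_terms(),
                                  covariates = default_covariates(),
                                  method = c("ML", "REML")) {
  method <- match.arg(method)
  if (!modifier %in% names(panel)) stop("modifier not in panel: ", modifier)
  if (length(unique(panel[[modifier]])) < 2) {
    stop("modifier is constant; no interaction is estimable")
  }
  terms <- unique(c(exposures, covariates, modifier,
                    paste0(exposure, ":", modifier)))
  res <- lmm_fit(panel, terms, reml = method == "REML")
  structure(list(
    tidy = tidy_fixed(res$fit),
    varcomp = variance_components(res$fit),
    converged = res$converged, messages = res$messages,
    n_obs = nrow(res$panel),
    n_participants = length(unique(res$panel$participant_id)),
    method = method, fit = res$fit, data = res$panel,
    exposure = exposure, modifier = modifier, terms = terms),
    class = "model_result")
}

#' @keywords internal
interaction_coef_name <- function(coefs, exposure, pattern) {
  hit <- coefs[grepl(":", coefs) &
                 grepl(exposure, coefs, fixed = TRUE) &
                 grepl(pattern, coefs, fixed = TRUE)]
  if (length(hit) == 0) stop("no interaction coefficient found for ",
                             exposure, " x ", pattern)
  hit
}

#' Simple slopes of an exposure at levels of a modifier
#'
#' For a continuous modifier, the slope at level m is
#' `beta_exposure + beta_interaction * m`, with delta-method standard error
#' from the fixed-effects covariance; default levels are the panel mean and
#' +/-1 SD. For a categorical modifier, one slope per category. Slopes are
#' exponentiated after interval construction on the log scale.
#'
#' @param result A `model_result` from [fit_interaction_model()].
#' @param levels Optional numeric levels of a continuous modifier.
#' @return Data.frame: level, slope on the log scale, SE, exponentiated
#'   slope with 95% CI, p.
#' @export
simple_slopes <- function(result, levels = NULL) {
  fit <- result$fit
  exposure <- result$exposure
  modifier <- result$modifier
  b <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  modcol <- result$data[[modifier]]
  q <- stats::qnorm(0.975)
  if (is.numeric(modcol)) {
    if (is.null(levels)) {
      m <- mean(modcol); s <- stats::sd(modcol)
      levels <- c(`-1SD` = m - s, mean = m, `+1SD` = m + s)
    } else if (is.null(names(levels))) {
      names(levels) <- format(levels)
    }
    out_of_range <- levels < min(modcol) | levels > max(modcol)
    if (any(out_of_range)) {
      warning("modifier level(s) outside the observed range: ",
              paste(names(levels)[out_of_range], collapse = ", "))
    }
    iname <- interaction_coef_name(names(b), exposure, modifier)[1]
    slope <- b[[exposure]] + b[[iname]] * levels
    se <- sqrt(V[exposure, exposure] + levels^2 * V[iname, iname] +
                 2 * levels * V[exposure, iname])
    lev_lab <- names(levels)
  } else {
    levs <- levels(factor(modcol))
    slope <- se <- numeric(length(levs))
    for (j in seq_along(levs)) {
      iname <- paste0(exposure, ":", modifier, levs[j])
      alt <- paste0(modifier, levs[j], ":", exposure)
      iname <- if (iname %in% names(b)) iname else alt
      if (j == 1 && !iname %in% names(b)) {  # reference category
        slope[j] <- b[[exposure]]
        se[j] <- sqrt(V[exposure, exposure])
      } else {
        slope[j] <- b[[exposure]] + b[[iname]]
        se[j] <- sqrt(V[exposure, exposure] + V[iname, iname] +
                        2 * V[exposure, iname])
      }
    }
    lev_lab <- levs
    levels <- seq_along(levs)
  }
  data.frame(
    modifier = modifier, exposure = exposure, level = lev_lab,
    slope_log = as.numeric(slope), se = as.numeric(se),
    slope_exp = exp(as.numeric(slope)),
    ci_low = exp(as.numeric(slope) - q * se),
    ci_high = exp(as.numeric(slope) + q * se),
    p = 2 * stats::pnorm(-abs(as.numeric(slope) / as.numeric(se))),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Predicted MVPA trajectories over an exposure grid
#'
#' Fixed-effects predictions of the log outcome over a grid of exposure
#' values at each modifier level, holding every other covariate at its
#' panel mean (numeric) or reference level (categorical), back-transformed
#' to minutes per day.
#'
#' @param result A `model_result` from [fit_interaction_model()].
#' @param exposure_values Numeric grid for the exposure (default: 25 points
#'   over its observed range).
#' @param modifier_levels Levels of the modifier (default: mean and +/-1 SD
#'   if continuous, all categories if categorical).
#' @return Data.frame: exposure value, modifier level, predicted log
#'   outcome and predicted MVPA minutes.
#' @export
predicted_trajectories <- function(result, exposure_values = NULL,
                                   modifier_levels = NULL) {
  fit <- result$fit
  data <- result$data
  exposure <- result$exposure
  modifier <- result$modifier
  if (is.null(exposure_values)) {
    r <- range(data[[exposure]])
    exposure_values <- seq(r[1], r[2], length.out = 25)
  }
  modcol <- data[[modifier]]
  if (is.null(modifier_levels)) {
    modifier_levels <- if (is.numeric(modcol)) {
      m <- mean(modcol); s <- stats::sd(modcol)
      c(m - s, m, m + s)
    } else {
      levels(factor(modcol))
    }
  }
  grid <- expand.grid(exposure_values, modifier_levels,
                      stringsAsFactors = FALSE)
  names(grid) <- c(exposure, modifier)
  newdata <- grid
  for (v in setdiff(all.vars(stats::formula(fit, fixed.only = TRUE)),
                    c("log_mvpa", exposure, modifier))) {
    col <- data[[v]]
    newdata[[v]] <- if (is.numeric(col)) mean(col) else levels(factor(col))[1]
  }
  pred <- stats::predict(fit, newdata = newdata, re.form = NA)
  data.frame(grid, pred_log = as.numeric(pred),
             pred_minutes = back_transform_outcome(as.numeric(pred)),
             stringsAsFactors = FALSE)
}
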