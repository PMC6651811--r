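#' Cognitive outcome registry
#'
#' The thirteen modelled outcomes: response speed and accuracy for the five
#' computerised tasks (simple reaction time, choice reaction time, working
#' memory, visual recognition memory, response inhibition), total maze-learning
#' errors, and the two Stroop interference ratios. Each row records the
#' outcome's metric, its variance-stabilising transform, raw-scale baseline
#' and follow-up anchors (median and quartiles, used to give synthetic cohorts
#' realistic score distributions), and the default generating coefficients for
#' the low- and higher-exposure dummies used in parameter-recovery
#' experiments.
#'
#' Anchors and default exposure coefficients reproduce the descriptive and
#' adjusted-regression summaries of the source cohort: e.g. response-inhibition
#' speed has baseline median 632 ms (IQR 556-720), follow-up median 578 ms,
#' and default low/higher coefficients -0.023 / -0.024 on the log10 scale.
#'
#' @return Data frame, one row per outcome, with columns `outcome`, `task`,
#'   `metric`, `transform`, `base_med`, `base_q1`, `base_q3`, `fu_med`,
#'   `beta_low`, `beta_higher`, `ci_halfwidth_low`.
#' @export
outcome_registry <- function() {
  df <- data.frame(
    outcome = c("detection_speed", "detection_accuracy",
                "identification_speed", "identification_accuracy",
                "one_back_speed", "one_back_accuracy",
                "one_card_speed", "one_card_accuracy",
                "go_nogo_speed", "go_nogo_accuracy",
                "groton_maze_errors", "stroop_ab_ratio", "stroop_cd_ratio"),
    task = c("detection", "detection", "identification", "identification",
             "one_back", "one_back", "one_card", "one_card",
             "go_nogo", "go_nogo", "groton_maze", "stroop_ab", "stroop_cd"),
    metric = c("speed_ms", "accuracy_pct", "speed_ms", "accuracy_pct",
               "speed_ms", "accuracy_pct", "speed_ms", "accuracy_pct",
               "speed_ms", "accuracy_pct", "error_count", "time_ratio",
               "time_ratio"),
    transform = c("log10", "arcsine_sqrt", "log10", "arcsine_sqrt",
                  "log10", "arcsine_sqrt", "log10", "arcsine_sqrt",
                  "log10", "arcsine_sqrt", "identity", "identity", "identity"),
    base_med = c(348, 97, 596, 94, 972, 89, 1103, 59, 632, 96, 69, 0.09, 0.69),
    base_q1  = c(304, 90, 528, 86, 800, 76, 885, 49, 556, 94, 54, 0.02, 0.54),
    base_q3  = c(415, 100, 683, 97, 1125, 94, 1324, 65, 720, 100, 84, 0.17, 0.90),
    fu_med   = c(317, 97, 542, 94, 865, 91, 1033, 64, 578, 98, 56, 0.11, 0.65),
    beta_low = c(-0.015, -0.002, 0.001, 0.006, 0.013, 0.001, 0.001, 0.005,
                 -0.023, -0.014, 4.53, 0.034, -0.036),
    beta_higher = c(-0.0002, 0.002, -0.010, 0.028, -0.0001, -0.030, 0.009,
                    -0.016, -0.024, -0.002, 1.77, 0.004, -0.042),
    ci_halfwidth_low = c(0.020, 0.0465, 0.0215, 0.0435, 0.024, 0.0495,
                         0.0245, 0.027, 0.019, 0.030, 3.43, 0.0335, 0.081),
    stringsAsFactors = FALSE
  )
  df
}

# Transformed-scale anchors for one registry row: location and spread of the
# baseline score and the follow-up location, via the outcome's own transform.
# Accuracy anchors are percentages; quartile ceilings at 100% are nudged
# inside the domain before transforming. Spread uses the normal IQR/1.349
# equivalence.
transformed_anchors <- function(row) {
  tf <- function(x) {
    if (row$transform == "arcsine_sqrt") x <- pmin(x / 100, 0.995)
    apply_transform(x, row$transform)
  }
  mu_base <- tf(row$base_med)
  sd_base <- (tf(row$base_q3) - tf(row$base_q1)) / (2 * stats::qnorm(0.75))
  list(mu_base = mu_base, sd_base = max(sd_base, 1e-6), mu_fu = tf(row$fu_med))
}

#' Default generating coefficients and noise for synthetic outcomes
#'
#' Builds the per-outcome generating specification used by
#' [generate_cohort()]: true coefficients for the design-matrix columns and
#' the residual / school-level noise standard deviations, all on the
#' transformed analysis scale.
#'
#' The exposure-dummy coefficients default to the registry's adjusted
#' estimates. The residual SD is calibrated so that single-cohort
#' cluster-robust confidence intervals for the low-exposure coefficient have
#' approximately the registry's half-width: with group sizes
#' \eqn{n_{low}} and \eqn{n_{none}}, the target standard error
#' `ci_halfwidth_low / t(0.975, G-1)` is divided by
#' \eqn{\sqrt{1/n_{low} + 1/n_{none}}}, the leading design factor for a dummy
#' contrast against the reference group. The school random-intercept SD
#' defaults to 0.3 of the residual SD. Covariate effects are small multiples
#' of the baseline-score spread so every adjustment variable carries signal
#' without dominating the exposure contrasts; the baseline-score coefficient
#' is 0.5 (tracking of cognitive performance across waves).
#'
#' @param registry Outcome registry rows (default all thirteen outcomes).
#' @param n_low,n_none,n_schools Group sizes used in the residual-SD
#'   calibration (defaults: the 84 / 219 / 36 structure of the study cohort).
#' @param school_sd_scale School SD as a fraction of residual SD.
#' @return Data frame with one row per outcome: transform, `intercept`,
#'   `beta_low`, `beta_higher`, covariate coefficients (`beta_age`,
#'   `beta_sex`, `beta_cob`, `beta_pa`, `beta_ses`, `beta_time`,
#'   `beta_baseline`, `beta_gaming`, `beta_sex_gaming`), `mu_baseline`,
#'   `sd_baseline`, `residual_sd`, `school_sd`.
#' @export
outcome_defaults <- function(registry = outcome_registry(),
                             n_low = 84, n_none = 219, n_schools = 36,
                             school_sd_scale = 0.3) {
  stopifnot(n_low > 0, n_none > 0, n_schools > 1)
  out <- lapply(seq_len(nrow(registry)), function(j) {
    row <- registry[j, ]
    an <- transformed_anchors(row)
    se_target <- row$ci_halfwidth_low / stats::qt(0.975, n_schools - 1)
    resid_sd <- se_target / sqrt(1 / n_low + 1 / n_none)
    s <- an$sd_base
    data.frame(
      outcome = row$outcome, transform = row$transform,
      intercept = an$mu_fu - 0.5 * an$mu_base,
      beta_low = row$beta_low, beta_higher = row$beta_higher,
      beta_age = -0.05 * s, beta_sex = 0.05 * s, beta_cob = 0.02 * s,
      beta_pa = 0.01 * s, beta_ses = -0.02 * s, beta_time = -0.10 * s,
      beta_baseline = 0.5, beta_gaming = 0.02 * s, beta_sex_gaming = -0.01 * s,
      mu_baseline = an$mu_base, sd_baseline = s,
      residual_sd = resid_sd, school_sd = school_sd_scale * resid_sd,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
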