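fixture_midpoints_of <- function(cohort) {
  iv <- interval_from_reports(cohort$baseline_calls, cohort$followup_calls)
  (iv$lower + iv$upper) / 2
}

test_that("default fixture reproduces the printed exposure-group structure", {
  fx <- build_table1_fixture()
  cls <- classify_exposure(interval_from_reports(fx$baseline_calls, fx$followup_calls))
  expect_equal(as.numeric(table(cls)), c(219, 84, 79))
  mid <- fixture_midpoints_of(fx)
  expect_equal(unname(median(mid[cls == "low"])), 1, tolerance = 0.05)
  # quartile calibration within +/- 0.05 calls/week for both exposed groups
  expect_equal(unname(quantile(mid[cls == "low"], c(0.25, 0.5, 0.75))),
               c(0.5, 1, 1.5), tolerance = 0.05)
  expect_equal(unname(quantile(mid[cls == "higher"], c(0.25, 0.5, 0.75))),
               c(3, 5, 7.5), tolerance = 0.05)
  # exposed-group mean solved exactly
  expect_equal(mean(mid[cls != "none"]), 3.42, tolerance = 1e-9)
  # never-users are point intervals at zero
  expect_true(all(fx$baseline_calls[cls == "none"] == 0))
  expect_true(all(fx$followup_calls[cls == "none"] == 0))
})

test_that("fixture construction is deterministic and RNG-free", {
  set.seed(1); fx1 <- build_table1_fixture()
  set.seed(2); fx2 <- build_table1_fixture()
  expect_identical(fx1, fx2)
})

test_that("degenerate one-participant grid collapses to the median target", {
  cfg <- cohort_config(n_none = 1, n_low = 1, n_higher = 0,
                       midpoint_quantiles_low = c(1, 1, 1),
                       exposed_mean_target = 1)
  fx <- build_table1_fixture(cfg)
  expect_equal(fixture_midpoints_of(fx)[2], 1)
})

test_that("infeasible mean targets raise a calibration error", {
  cfg <- cohort_config(exposed_mean_target = 1)
  expect_error(build_table1_fixture(cfg), "calibration error")
  expect_error(generate_cohort(cfg, seed = 1), "calibration error")
})

test_that("configuration invariants are enforced with named violations", {
  expect_error(cohort_config(n_none = -1), "non-negative")
  expect_error(cohort_config(midpoint_quantiles_low = c(2, 1, 3)), "non-decreasing")
  expect_error(cohort_config(midpoint_quantiles_low = c(1, 1.8, 2.5)), "threshold")
  expect_error(cohort_config(midpoint_quantiles_higher = c(1, 5, 7.5)), "25th percentile")
  expect_error(cohort_config(interval_halfwidth_fraction = 1), "halfwidth")
})

test_that("generated cohorts are byte-identical under identical config and seed", {
  cfg <- small_config()
  c1 <- generate_cohort(cfg, seed = 31)
  c2 <- generate_cohort(cfg, seed = 31)
  expect_identical(c1, c2)
  c3 <- generate_cohort(cfg, seed = 32)
  expect_false(identical(c1$followup_calls, c3$followup_calls))
})

test_that("generated exposure honours group structure and interval geometry", {
  cfg <- small_config()
  co <- generate_cohort(cfg, seed = 5)
  cls <- classify_exposure(interval_from_reports(co$baseline_calls, co$followup_calls))
  expect_equal(as.numeric(table(cls)), c(60, 30, 30))
  expect_equal(as.character(cls), as.character(co$group))
  mid <- fixture_midpoints_of(co)
  exp_rows <- co$group != "none"
  hw <- (co$followup_calls - co$baseline_calls)[exp_rows] / 2
  expect_equal(hw, 0.4 * mid[exp_rows], tolerance = 1e-12)
  expect_true(all(co$ses_quintile %in% 1:5))
  expect_true(all(co$time_between_exams > 0))
  expect_true(all(co$school_id %in% sprintf("S%02d", 1:12)))
  expect_equal(anyDuplicated(co$participant_id), 0L)
})

test_that("generated outcomes match their linear predictor mean over replicates", {
  cfg <- small_config(outcomes = "go_nogo_speed")
  spec <- cfg$outcomes
  means <- vapply(1:200, function(r) {
    co <- generate_cohort(cfg, seed = 1000 + r, outcomes = "go_nogo_speed")
    lp <- spec$intercept +
      spec$beta_low * (co$group == "low") +
      spec$beta_higher * (co$group == "higher") +
      spec$beta_age * co$age + spec$beta_sex * co$sex +
      spec$beta_cob * co$country_of_birth + spec$beta_pa * co$physical_activity +
      spec$beta_ses * co$ses_quintile + spec$beta_time * co$time_between_exams +
      spec$beta_baseline * co$go_nogo_speed_baseline +
      spec$beta_gaming * co$gaming_quintile +
      spec$beta_sex_gaming * co$sex * co$gaming_quintile
    mean(co$go_nogo_speed_followup) - mean(lp)
  }, 1)
  mc_se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means)), 3 * mc_se + 1e-12)
})

test_that("null-effect cohorts yield exposure estimates centred on zero", {
  cfg <- null_config(outcomes = "go_nogo_speed")
  est <- vapply(1:60, function(r) {
    co <- generate_cohort(cfg, seed = 2000 + r, outcomes = "go_nogo_speed")
    fit <- fit_outcome(co, "go_nogo_speed")
    fit$table$estimate[fit$table$term == "exp_low"]
  }, 1)
  expect_lt(abs(mean(est)), 3 * sd(est) / sqrt(length(est)))
})
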