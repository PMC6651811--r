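# Brute-force CR1 sandwich: explicit loops over clusters, used as the
# independent oracle for the matrix implementation.
brute_force_cr1 <- function(X, u, cluster) {
  XtX_inv <- solve(t(X) %*% X)
  meat <- matrix(0, ncol(X), ncol(X))
  for (g in unique(cluster)) {
    idx <- which(cluster == g)
    sg <- t(X[idx, , drop = FALSE]) %*% u[idx]
    meat <- meat + sg %*% t(sg)
  }
  G <- length(unique(cluster)); N <- nrow(X); k <- ncol(X)
  (G / (G - 1)) * ((N - 1) / (N - k)) * XtX_inv %*% meat %*% XtX_inv
}

toy_design <- function(n = 6, seed = 3) {
  set.seed(seed)
  X <- cbind(`(Intercept)` = 1, x1 = rnorm(n), x2 = runif(n))
  y <- 1 + 2 * X[, 2] - X[, 3] + rnorm(n, 0, 0.3)
  list(X = X, y = y, cluster = rep(c("a", "b"), length.out = n))
}

test_that("OLS via QR matches the explicit normal-equation oracle", {
  td <- toy_design()
  fit <- fit_ols(td$X, td$y)
  beta_oracle <- solve(t(td$X) %*% td$X) %*% t(td$X) %*% td$y
  expect_equal(unname(fit$coefficients), as.numeric(beta_oracle), tolerance = 1e-10)
  expect_lt(max(abs(t(td$X) %*% fit$residuals)), 1e-10)
})

test_that("OLS degenerate cases: exact fit and intercept-only mean", {
  td <- toy_design()
  y_lin <- td$X %*% c(1, 2, 3)
  expect_lt(max(abs(fit_ols(td$X, as.numeric(y_lin))$residuals)), 1e-10)
  fit <- fit_ols(matrix(1, 5, 1), c(1, 2, 3, 4, 10))
  expect_equal(unname(fit$coefficients), 4)
  expect_error(fit_ols(cbind(1, c(1, 1, 1), c(2, 2, 2)), 1:3), "singular")
})

test_that("CR1 sandwich matches the brute-force cluster-loop oracle", {
  td <- toy_design(n = 12, seed = 11)
  cl <- rep(c("a", "b", "c"), each = 4)
  fit <- fit_ols(td$X, td$y)
  V <- cluster_robust_vcov(td$X, fit$residuals, cl)
  expect_equal(V, brute_force_cr1(td$X, fit$residuals, cl), tolerance = 1e-10)
  expect_true(isSymmetric(V))
  expect_true(all(eigen(V, only.values = TRUE)$values > -1e-12))
})

test_that("CR1 reduces to the scaled heteroskedasticity-robust estimator for singleton clusters", {
  td <- toy_design(n = 9, seed = 13)
  fit <- fit_ols(td$X, td$y)
  u <- fit$residuals
  V_cl <- cluster_robust_vcov(td$X, u, as.character(1:9))
  XtX_inv <- solve(t(td$X) %*% td$X)
  hc <- XtX_inv %*% (t(td$X) %*% diag(u^2) %*% td$X) %*% XtX_inv
  c_adj <- (9 / 8) * (8 / (9 - 3))
  expect_equal(V_cl, c_adj * hc, tolerance = 1e-10)
})

test_that("zero residuals give a zero covariance and collapsed intervals", {
  td <- toy_design()
  V <- cluster_robust_vcov(td$X, rep(0, 6), td$cluster)
  expect_equal(max(abs(V)), 0)
  ci <- confidence_intervals(c(a = -0.023), matrix(0), G = 36)
  expect_equal(ci$ci_lower, ci$estimate)
  expect_equal(ci$ci_upper, ci$estimate)
})

test_that("CR1 agrees with the clustered-sandwich reference implementation", {
  skip_if_not_installed("sandwich")
  co <- generate_cohort(small_config(outcomes = "go_nogo_speed"), seed = 17)
  dm <- build_design(co, "go_nogo_speed")
  df <- as.data.frame(dm$X[, -1]); df$y <- dm$y
  m <- stats::lm(y ~ ., data = df)
  V_ref <- sandwich::vcovCL(m, cluster = dm$cluster, type = "HC1", cadjust = TRUE)
  V_ours <- cluster_robust_vcov(dm$X, stats::resid(m), dm$cluster)
  expect_equal(max(abs(V_ours - unname(V_ref))), 0, tolerance = 1e-10)
})

test_that("t(G-1) intervals and p-values follow the reference distribution", {
  ci <- confidence_intervals(c(b = -0.023), matrix(0.0097^2), G = 36)
  expect_equal(ci$ci_lower, -0.023 - qt(0.975, 35) * 0.0097)
  expect_equal(c(round(ci$ci_lower, 3), round(ci$ci_upper, 3)), c(-0.043, -0.003))
  expect_equal(confidence_intervals(c(b = 0), matrix(4), G = 10)$p_value, 1)
  expect_error(confidence_intervals(c(b = 1), matrix(1), G = 1), "G")
})

test_that("design matrix has the documented structure on the fixture cohort", {
  cfg <- cohort_config()
  fx <- build_table1_fixture(cfg)
  fx <- exposim:::attach_covariates_outcomes(fx, cfg, seed = 99,
                                             outcomes = "go_nogo_speed")
  dm <- build_design(fx, "go_nogo_speed")
  expect_equal(colnames(dm$X),
               c("(Intercept)", "exp_low", "exp_higher", "age", "sex",
                 "country_of_birth", "physical_activity", "ses_quintile",
                 "time_between_exams", "baseline", "gaming_quintile",
                 "sex_gaming"))
  expect_equal(sum(dm$X[, "exp_low"]), 84)
  expect_equal(sum(dm$X[, "exp_higher"]), 79)
  expect_equal(dm$n_dropped, 0)
})

test_that("degenerate designs are rejected with informative errors", {
  cfg <- small_config(n_low = 0, n_higher = 0, outcomes = "go_nogo_speed")
  co <- generate_cohort(cfg, seed = 21)
  expect_error(build_design(co, "go_nogo_speed"), "collinear")
  one_school <- generate_cohort(small_config(outcomes = "go_nogo_speed"), seed = 22)
  one_school$school_id <- "S01"
  expect_error(build_design(one_school, "go_nogo_speed"), "two clusters")
})

test_that("complete-case filtering drops and counts rows with missing fields", {
  co <- generate_cohort(small_config(outcomes = "go_nogo_speed"), seed = 23)
  co$age[c(3, 10)] <- NA
  dm <- build_design(co, "go_nogo_speed")
  expect_equal(dm$n_dropped, 2)
  expect_equal(nrow(dm$X), nrow(co) - 2)
})

test_that("coefficients and robust SEs are scale equivariant", {
  co <- generate_cohort(small_config(outcomes = "go_nogo_speed"), seed = 29)
  f1 <- fit_outcome(co, "go_nogo_speed")
  co2 <- co
  co2$go_nogo_speed_followup <- 10 * co2$go_nogo_speed_followup
  co2$go_nogo_speed_baseline <- co$go_nogo_speed_baseline
  f2 <- fit_outcome(co2, "go_nogo_speed")
  i <- f1$table$term == "exp_low"
  expect_equal(f2$table$estimate[i], 10 * f1$table$estimate[i], tolerance = 1e-10)
  expect_equal(f2$table$se[i], 10 * f1$table$se[i], tolerance = 1e-10)
})

test_that("categorical gaming coding expands the interaction into quintile dummies", {
  co <- generate_cohort(small_config(outcomes = "go_nogo_speed"), seed = 37)
  dm <- build_design(co, "go_nogo_speed", gaming_categorical = TRUE)
  expect_true(all(c("gaming_q2", "sex_gaming_q5") %in% colnames(dm$X)))
  fit <- fit_outcome(co, "go_nogo_speed", gaming_categorical = TRUE)
  expect_s3_class(fit, "exposure_fit")
})
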