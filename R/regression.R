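#' @title Adjusted cluster-robust regression
#' @name regression
#' @description Builds the adjusted design for one transformed cognitive
#'   outcome (exposure-group dummies against the never-user reference plus
#'   the confounder set), fits ordinary least squares, and performs inference
#'   with the CR1 school-clustered sandwich covariance and t(G-1) critical
#'   values.
NULL

# Documented fixed column order of the design matrix.
design_columns <- function() {
  c("(Intercept)", "exp_low", "exp_higher", "age", "sex", "country_of_birth",
    "physical_activity", "ses_quintile", "time_between_exams", "baseline",
    "gaming_quintile", "sex_gaming")
}

#' Build the design matrix for one outcome
#'
#' Assembles response, predictors, and cluster ids for a transformed outcome:
#' intercept; low and higher exposure dummies (reference = never-users,
#' classification by [classify_exposure()] on the participant's exposure
#' interval); age; sex; country of birth; physical activity; socioeconomic
#' quintile; time between examinations; baseline transformed score; console
#' gaming quintile; and the sex-by-gaming interaction (product of the sex
#' indicator with the gaming quintile score, or with quintile indicator
#' columns when `gaming_categorical = TRUE`). Rows with any missing field are
#' dropped (complete-case analysis) and the dropped count is attached.
#'
#' @param cohort A cohort table on the transformed scale.
#' @param outcome Outcome name (a row of [outcome_registry()]).
#' @param threshold Classification threshold in calls/week.
#' @param gaming_categorical Expand the gaming quintile (and its interaction)
#'   into indicator columns instead of an integer score.
#' @return List with `X` (numeric matrix, fixed column order), `y`,
#'   `cluster` (school ids), and `n_dropped`.
#' @export
build_design <- function(cohort, outcome, threshold = 2,
                         gaming_categorical = FALSE) {
  fu_col <- paste0(outcome, "_followup")
  base_col <- paste0(outcome, "_baseline")
  needed <- c("school_id", "baseline_calls", "followup_calls", "age", "sex",
              "country_of_birth", "physical_activity", "ses_quintile",
              "time_between_exams", "gaming_quintile", base_col, fu_col)
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  cc <- stats::complete.cases(cohort[needed])
  n_dropped <- sum(!cc)
  d <- cohort[cc, , drop = FALSE]
  if (nrow(d) < 2) stop("fewer than two complete cases", call. = FALSE)

  cls <- classify_exposure(interval_from_reports(d$baseline_calls, d$followup_calls),
                           threshold)
  X <- cbind(
    `(Intercept)` = 1,
    exp_low = as.numeric(cls == "low"),
    exp_higher = as.numeric(cls == "higher"),
    age = d$age,
    sex = d$sex,
    country_of_birth = d$country_of_birth,
    physical_activity = d$physical_activity,
    ses_quintile = d$ses_quintile,
    time_between_exams = d$time_between_exams,
    baseline = d[[base_col]],
    gaming_quintile = d$gaming_quintile,
    sex_gaming = d$sex * d$gaming_quintile
  )
  if (gaming_categorical) {
    gq <- factor(d$gaming_quintile, levels = 1:5)
    G <- stats::model.matrix(~gq)[, -1, drop = FALSE]
    colnames(G) <- paste0("gaming_q", 2:5)
    X <- X[, setdiff(colnames(X), c("gaming_quintile", "sex_gaming")), drop = FALSE]
    X <- cbind(X, G, G * d$sex)
    colnames(X)[(ncol(X) - 3):ncol(X)] <- paste0("sex_gaming_q", 2:5)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  cluster <- as.character(d$school_id)
  if (length(unique(cluster)) < 2) stop("at least two clusters (schools) required",
                                        call. = FALSE)
  list(X = X, y = d[[fu_col]], cluster = cluster, n_dropped = n_dropped)
}

#' Ordinary least squares via QR
#'
#' @param X Full-rank numeric design matrix.
#' @param y Response vector.
#' @return List with `coefficients`, `residuals`, `fitted`.
#' @export
fit_ols <- function(X, y) {
  stopifnot(nrow(X) == length(y))
  fit <- stats::lm.fit(X, y)
  if (anyNA(fit$coefficients)) stop("singular design matrix", call. = FALSE)
  list(coefficients = fit$coefficients,
       residuals = as.numeric(fit$residuals),
       fitted = as.numeric(fit$fitted.values))
}

#' CR1 cluster-robust sandwich covariance
#'
#' Sandwich estimator allowing arbitrary residual correlation within clusters:
#' \deqn{V = c \, (X'X)^{-1} \Big(\sum_g X_g' u_g u_g' X_g\Big) (X'X)^{-1}}
#' with the CR1 small-sample factor
#' \eqn{c = \frac{G}{G-1}\cdot\frac{N-1}{N-k}}, the convention of standard
#' clustered-regression software. With every observation its own cluster this
#' reduces to the heteroskedasticity-robust estimator scaled by the same
#' factor.
#'
#' @param X Design matrix used in the fit.
#' @param residuals OLS residuals.
#' @param cluster Cluster id per row (>= 2 distinct values).
#' @return Symmetric positive-semidefinite covariance matrix for the
#'   coefficients.
#' @export
cluster_robust_vcov <- function(X, residuals, cluster) {
  N <- nrow(X); k <- ncol(X)
  if (length(residuals) != N) stop("residuals must have one value per row", call. = FALSE)
  if (length(cluster) != N || anyNA(cluster)) {
    stop("cluster ids must cover every row", call. = FALSE)
  }
  G <- length(unique(cluster))
  if (G < 2) stop("at least two clusters required", call. = FALSE)
  bread <- solve(crossprod(X))
  # cluster score sums: rows of (X * u) aggregated within cluster
  scores <- rowsum(X * residuals, group = cluster)
  meat <- crossprod(as.matrix(scores))
  c_adj <- (G / (G - 1)) * ((N - 1) / (N - k))
  V <- c_adj * bread %*% meat %*% bread
  (V + t(V)) / 2
}

#' Confidence intervals and p-values with t(G-1) reference
#'
#' Robust standard errors are the square roots of the covariance diagonal;
#' intervals are \eqn{\hat\beta \pm t_{G-1,\,1-\alpha/2}\,\mathrm{SE}} and
#' p-values come from the t distribution with G-1 degrees of freedom, G the
#' number of clusters.
#'
#' @param coefficients Coefficient vector.
#' @param vcov Robust covariance matrix.
#' @param G Number of clusters.
#' @param level Confidence level (default 0.95).
#' @return Data frame with `term`, `estimate`, `se`, `ci_lower`, `ci_upper`,
#'   `p_value`.
#' @export
confidence_intervals <- function(coefficients, vcov, G, level = 0.95) {
  stopifnot(level > 0, level < 1, G >= 2)
  se <- sqrt(diag(vcov))
  tcrit <- stats::qt(1 - (1 - level) / 2, df = G - 1)
  tstat <- ifelse(se > 0, coefficients / se, ifelse(coefficients == 0, 0, Inf))
  data.frame(term = names(coefficients),
             estimate = as.numeric(coefficients),
             se = as.numeric(se),
             ci_lower = as.numeric(coefficients - tcrit * se),
             ci_upper = as.numeric(coefficients + tcrit * se),
             p_value = 2 * stats::pt(-abs(tstat), df = G - 1),
             row.names = NULL)
}

#' Fit the adjusted model for one outcome
#'
#' End-to-end wrapper: design construction, OLS fit, CR1 clustered
#' covariance, and t(G-1) inference.
#'
#' @inheritParams build_design
#' @param level Confidence level.
#' @return An `exposure_fit` with the coefficient table, covariance, cluster
#'   count `G`, observations `N`, predictors `k`, and dropped-row count.
#' @export
fit_outcome <- function(cohort, outcome, threshold = 2, level = 0.95,
                        gaming_categorical = FALSE) {
  dm <- build_design(cohort, outcome, threshold = threshold,
                     gaming_categorical = gaming_categorical)
  ols <- fit_ols(dm$X, dm$y)
  V <- cluster_robust_vcov(dm$X, ols$residuals, dm$cluster)
  G <- length(unique(dm$cluster))
  ci <- confidence_intervals(ols$coefficients, V, G, level = level)
  structure(list(outcome = outcome, table = ci, vcov = V,
                 coefficients = ols$coefficients, residuals = ols$residuals,
                 G = G, N = nrow(dm$X), k = ncol(dm$X),
                 n_dropped = dm$n_dropped, level = level),
            class = "exposure_fit")
}

#' @export
print.exposure_fit <- function(x, ...) {
  cat(sprintf("Adjusted cluster-robust fit: %s (N = %d, G = %d schools, k = %d)\n",
              x$outcome, x$N, x$G, x$k))
  rows <- x$table[x$table$term %in% c("exp_low", "exp_higher"), ]
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    cat(sprintf("  %-10s %9.4f  [%8.4f, %8.4f]  p = %.3f%s\n", r$term,
                r$estimate, r$ci_lower, r$ci_upper, r$p_value,
                if (r$p_value <= 0.05) " *" else ""))
  }
  invisible(x)
}

#' Exposure-effect report across outcomes
#'
#' Fits every requested outcome and tabulates the low- and higher-exposure
#' coefficients, reproducing the layout of an adjusted difference-in-means
#' table: one row per outcome and exposure group with estimate, robust SE,
#' confidence bounds, p-value, and a significance flag at 0.05.
#'
#' @inheritParams fit_outcome
#' @param outcomes Character vector of outcome names (default: all registry
#'   outcomes present in the cohort).
#' @return Data frame with one row per outcome x exposure group.
#' @export
regression_report <- function(cohort, outcomes = NULL, threshold = 2,
                              level = 0.95) {
  if (is.null(outcomes)) {
    reg <- outcome_registry()$outcome
    outcomes <- reg[paste0(reg, "_followup") %in% names(cohort)]
  }
  rows <- lapply(outcomes, function(o) {
    fit <- fit_outcome(cohort, o, threshold = threshold, level = level)
    tb <- fit$table[fit$table$term %in% c("exp_low", "exp_higher"), ]
    data.frame(outcome = o,
               group = sub("exp_", "", tb$term),
               estimate = tb$estimate, se = tb$se,
               ci_lower = tb$ci_lower, ci_upper = tb$ci_upper,
               p_value = tb$p_value,
               significant = tb$p_value <= 0.05,
               N = fit$N, G = fit$G,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
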