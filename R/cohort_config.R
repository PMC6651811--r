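#' Synthetic cohort configuration
#'
#' Collects everything that defines a synthetic cohort: exposure-group sizes,
#' the quartile targets for the low and higher groups' interval midpoints, the
#' exposed-group mean target, the relative half-width of exposure intervals,
#' school clustering, and the per-outcome generating coefficients and noise.
#'
#' Defaults reproduce the study cohort's exposure structure: 219 never-users,
#' 84 low-exposure and 79 higher-exposure participants (382 complete cases)
#' across 36 schools, low-group midpoint quartiles (0.5, 1, 1.5) calls/week,
#' higher-group quartiles (3, 5, 7.5), and an exposed-group mean of 3.42
#' calls/week.
#'
#' @param n_none,n_low,n_higher Exposure-group sizes (non-negative integers).
#' @param n_schools Number of schools (clusters); participants are allocated
#'   round-robin so every school mixes exposure groups.
#' @param midpoint_quantiles_low,midpoint_quantiles_higher Non-decreasing
#'   triples: 25th, 50th and 75th percentiles of interval midpoints
#'   (calls/week) in each exposed group.
#' @param exposed_mean_target Target mean midpoint across the combined
#'   low + higher group (calls/week).
#' @param interval_halfwidth_fraction Half-width of each exposure interval as
#'   a fraction of its midpoint, in `[0, 1)`.
#' @param classification_threshold Calls/week threshold separating low from
#'   higher exposure (default 2).
#' @param outcomes Per-outcome generating specification, as produced by
#'   [outcome_defaults()]; edit its columns to change true coefficients or
#'   noise (e.g. set `beta_low` to 0 for a null-effect cohort).
#' @return A `cohort_config` list, validated against the structural
#'   invariants.
#' @export
cohort_config <- function(n_none = 219, n_low = 84, n_higher = 79,
                          n_schools = 36,
                          midpoint_quantiles_low = c(0.5, 1, 1.5),
                          midpoint_quantiles_higher = c(3, 5, 7.5),
                          exposed_mean_target = 3.42,
                          interval_halfwidth_fraction = 0.4,
                          classification_threshold = 2,
                          outcomes = outcome_defaults(
                            n_low = max(n_low, 1), n_none = max(n_none, 1),
                            n_schools = n_schools)) {
  cfg <- structure(list(
    n_none = as.integer(n_none), n_low = as.integer(n_low),
    n_higher = as.integer(n_higher), n_schools = as.integer(n_schools),
    midpoint_quantiles_low = as.numeric(midpoint_quantiles_low),
    midpoint_quantiles_higher = as.numeric(midpoint_quantiles_higher),
    exposed_mean_target = as.numeric(exposed_mean_target),
    interval_halfwidth_fraction = as.numeric(interval_halfwidth_fraction),
    classification_threshold = as.numeric(classification_threshold),
    outcomes = outcomes
  ), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

#' Validate a cohort configuration
#'
#' Checks the structural invariants and stops with a message naming the first
#' violated one.
#'
#' @param config A `cohort_config`.
#' @return The config, invisibly, if valid.
#' @export
validate_cohort_config <- function(config) {
  fail <- function(msg) stop("invalid cohort_config: ", msg, call. = FALSE)
  with(config, {
    if (any(c(n_none, n_low, n_higher) < 0)) fail("group sizes must be non-negative")
    if (n_schools < 1) fail("n_schools must be positive")
    for (nm in c("midpoint_quantiles_low", "midpoint_quantiles_higher")) {
      q <- config[[nm]]
      if (length(q) != 3) fail(paste(nm, "must be a (25th, 50th, 75th) triple"))
      if (is.unsorted(q)) fail(paste(nm, "must be non-decreasing"))
      if (any(q < 0)) fail(paste(nm, "must be non-negative"))
    }
    t <- classification_threshold
    if (t < 0) fail("classification_threshold must be non-negative")
    # low-group midpoints must stay strictly below the threshold: the grid's
    # linear upper tail tops out at q75 + (q75 - q50)
    qs <- midpoint_quantiles_low
    if (n_low > 0 && qs[3] + (qs[3] - qs[2]) > t) {
      fail("low-group midpoint quantiles imply midpoints above the classification threshold")
    }
    if (n_higher > 0 && midpoint_quantiles_higher[1] < t) {
      fail("higher-group 25th percentile must be at or above the classification threshold")
    }
    if (interval_halfwidth_fraction < 0 || interval_halfwidth_fraction >= 1) {
      fail("interval_halfwidth_fraction must be in [0, 1)")
    }
    if (exposed_mean_target < 0) fail("exposed_mean_target must be non-negative")
    if (!is.data.frame(outcomes) || nrow(outcomes) < 1) {
      fail("outcomes must be a non-empty generating specification")
    }
    if (any(outcomes$residual_sd < 0) || any(outcomes$school_sd < 0)) {
      fail("residual_sd and school_sd must be non-negative")
    }
  })
  invisible(config)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("cohort_config: %d none / %d low / %d higher across %d schools\n",
              x$n_none, x$n_low, x$n_higher, x$n_schools))
  cat(sprintf("  midpoint quartiles low (%.2g, %.2g, %.2g), higher (%.2g, %.2g, %.2g)\n",
              x$midpoint_quantiles_low[1], x$midpoint_quantiles_low[2],
              x$midpoint_quantiles_low[3], x$midpoint_quantiles_higher[1],
              x$midpoint_quantiles_higher[2], x$midpoint_quantiles_higher[3]))
  cat(sprintf("  exposed mean target %.3f calls/week, halfwidth fraction %.2f, threshold %.2g\n",
              x$exposed_mean_target, x$interval_halfwidth_fraction,
              x$classification_threshold))
  cat(sprintf("  %d outcomes configured\n", nrow(x$outcomes)))
  invisible(x)
}
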