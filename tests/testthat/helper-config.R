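# Small cohort configuration for fast replicate studies: same exposure
# structure as the default, scaled down, with noise recalibrated to the
# smaller group sizes.
small_config <- function(n_none = 60, n_low = 30, n_higher = 30,
                         n_schools = 12, outcomes = NULL) {
  cfg <- cohort_config(
    n_none = n_none, n_low = n_low, n_higher = n_higher, n_schools = n_schools,
    outcomes = outcome_defaults(n_low = max(n_low, 1), n_none = max(n_none, 1),
                                n_schools = n_schools)
  )
  if (!is.null(outcomes)) {
    cfg$outcomes <- cfg$outcomes[cfg$outcomes$outcome %in% outcomes, , drop = FALSE]
  }
  cfg
}

# Configuration with all exposure and covariate effects zeroed (null cohort).
null_config <- function(...) {
  cfg <- small_config(...)
  beta_cols <- grep("^beta_", names(cfg$outcomes), value = TRUE)
  cfg$outcomes[beta_cols] <- 0
  cfg
}
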