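#' Cohort table CSV round-trip
#'
#' The cohort CSV uses a fixed header: `participant_id`, `school_id`,
#' `baseline_calls`, `followup_calls`, `age`, `sex`, `country_of_birth`,
#' `physical_activity`, `ses_quintile`, `time_between_exams`,
#' `gaming_quintile`, then one column per outcome per wave
#' (`<outcome>_baseline`, `<outcome>_followup`). A `scale` comment is not
#' stored in the file; [read_cohort_csv()] takes it as an argument.
#'
#' @param cohort Cohort data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  lead <- c("participant_id", "school_id", "baseline_calls", "followup_calls",
            "age", "sex", "country_of_birth", "physical_activity",
            "ses_quintile", "time_between_exams", "gaming_quintile")
  present <- intersect(lead, names(cohort))
  rest <- setdiff(names(cohort), c(present, "group"))
  utils::write.csv(cohort[c(present, rest)], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @param scale Scale of the outcome columns in the file: `"raw"` scores
#'   (speeds in ms, accuracies in percent) or already `"transformed"`.
#' @export
read_cohort_csv <- function(path, scale = c("raw", "transformed")) {
  scale <- match.arg(scale)
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant_id", "school_id", "baseline_calls", "followup_calls")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols)) {
    stop("cohort file is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(cohort$participant_id)) {
    stop("participant_id values must be unique", call. = FALSE)
  }
  attr(cohort, "provenance") <- "loaded"
  attr(cohort, "scale") <- scale
  cohort
}

#' Write / read a cohort configuration as JSON or YAML
#'
#' The outcome generating specification is stored as a row-wise table; the
#' format is chosen from the file extension (`.json`, `.yml`, `.yaml`; YAML
#' requires the optional yaml package).
#'
#' @param config A [cohort_config()].
#' @param path File path ending in `.json`, `.yml`, or `.yaml`.
#' @return `path` (write) or the reconstructed, validated `cohort_config`
#'   (read).
#' @export
write_cohort_config <- function(config, path) {
  validate_cohort_config(config)
  x <- unclass(config)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required for YAML config files", call. = FALSE)
    }
    x$outcomes <- lapply(seq_len(nrow(config$outcomes)),
                         function(i) as.list(config$outcomes[i, ]))
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required for YAML config files", call. = FALSE)
    }
    y <- yaml::read_yaml(path)
    y$outcomes <- do.call(rbind, lapply(y$outcomes, as.data.frame))
    y
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cohort_config(
    n_none = x$n_none, n_low = x$n_low, n_higher = x$n_higher,
    n_schools = x$n_schools,
    midpoint_quantiles_low = x$midpoint_quantiles_low,
    midpoint_quantiles_higher = x$midpoint_quantiles_higher,
    exposed_mean_target = x$exposed_mean_target,
    interval_halfwidth_fraction = x$interval_halfwidth_fraction,
    classification_threshold = x$classification_threshold,
    outcomes = as.data.frame(x$outcomes)
  )
}
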