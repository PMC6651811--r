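#' Outcome transformations
#'
#' Cognitive scores are variance-stabilised before regression: mean response
#' times (ms) are base-10 log transformed, accuracies (proportions correct)
#' are arcsine square-root transformed, and Stroop form times are reduced to
#' relative interference ratios. Maze error counts and the Stroop ratios enter
#' the models untransformed.
#'
#' @name outcome-transforms
NULL

#' Base-10 log transform for response speeds
#'
#' @param rt Positive response times in milliseconds.
#' @return `log10(rt)`.
#' @examples
#' transform_speed(1000)  # 3
#' @export
transform_speed <- function(rt) {
  if (anyNA(rt)) stop("response time must not be NA", call. = FALSE)
  if (any(rt <= 0)) stop("response time must be positive", call. = FALSE)
  log10(rt)
}

#' Inverse of [transform_speed()]
#' @param x Log10 response time.
#' @return Response time in ms.
#' @export
inverse_speed <- function(x) 10^x

#' Arcsine square-root transform for accuracy proportions
#'
#' Percentages must be divided by 100 before transforming; the result is in
#' radians on \eqn{[0, \pi/2]}.
#'
#' @param p Proportions correct in \eqn{[0, 1]}.
#' @return `asin(sqrt(p))` in radians.
#' @examples
#' transform_accuracy(0.5)  # pi/4
#' @export
transform_accuracy <- function(p) {
  if (anyNA(p)) stop("accuracy must not be NA", call. = FALSE)
  if (any(p < 0 | p > 1)) {
    stop("accuracy must be a proportion in [0, 1]; divide percentages by 100",
         call. = FALSE)
  }
  asin(sqrt(p))
}

#' Inverse of [transform_accuracy()]
#' @param x Arcsine-transformed accuracy (radians).
#' @return Proportion in \eqn{[0, 1]}.
#' @export
inverse_accuracy <- function(x) sin(x)^2

#' Stroop interference time ratio
#'
#' Relative slow-down between two matched Stroop forms,
#' \eqn{(t_2 - t_1)/t_1}; form B is compared with form A and form D with
#' form C. Larger values indicate greater interference.
#'
#' @param t_first Completion time of the first form (seconds, > 0).
#' @param t_second Completion time of the second form (seconds).
#' @return The interference ratio (unitless), modelled untransformed.
#' @examples
#' stroop_ratio(100, 109)  # 0.09
#' @export
stroop_ratio <- function(t_first, t_second) {
  if (anyNA(t_first) || anyNA(t_second)) stop("form times must not be NA", call. = FALSE)
  if (any(t_first <= 0)) stop("first form time must be positive", call. = FALSE)
  (t_second - t_first) / t_first
}

# Transform a raw-scale value vector for a given transform tag.
apply_transform <- function(x, transform) {
  switch(transform,
         log10 = transform_speed(x),
         arcsine_sqrt = transform_accuracy(x),
         identity = x,
         stop("unknown transform: ", transform, call. = FALSE))
}

#' Transform all outcome columns of a cohort table
#'
#' Applies each outcome's transform (log10 for speeds, arcsine square root for
#' accuracy proportions, identity for error counts and ratios) to the
#' baseline and follow-up columns. Accuracy columns are expected as
#' percentages on the raw scale and are divided by 100 first. Cohorts already
#' on the transformed scale (as produced by the synthetic generator) are
#' returned unchanged.
#'
#' @param cohort A cohort data frame; its `scale` attribute (`"raw"` or
#'   `"transformed"`) records which scale the outcome columns are on.
#' @param outcomes Outcome registry rows to transform (default: all present).
#' @return The cohort with transformed outcome columns and
#'   `scale = "transformed"`.
#' @export
transform_cohort <- function(cohort, outcomes = outcome_registry()) {
  scale <- attr(cohort, "scale")
  if (identical(scale, "transformed")) return(cohort)
  for (j in seq_len(nrow(outcomes))) {
    o <- outcomes[j, ]
    for (wave in c("baseline", "followup")) {
      col <- paste0(o$outcome, "_", wave)
      if (!col %in% names(cohort)) next
      x <- cohort[[col]]
      if (o$transform == "arcsine_sqrt") x <- x / 100
      cohort[[col]] <- apply_transform(x, o$transform)
    }
  }
  attr(cohort, "scale") <- "transformed"
  cohort
}
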