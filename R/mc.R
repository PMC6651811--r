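#' @title Seeded Monte Carlo machinery
#' @description Internal RNG helpers plus the Latin Hypercube / simple random
#'   samplers and the participant- and group-level Monte Carlo runs.
#' @name mc
NULL

# Evaluate expr under a fixed Mersenne-Twister seed, restoring the caller's
# RNG state afterwards so package functions never perturb the global stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  force(expr)
}

#' Derive a stream seed from a master seed
#'
#' Every source of randomness in the package draws from a stream whose seed is
#' derived deterministically from a single master seed, a stage label, and an
#' index (e.g. a participant or replicate number). The mixing is a fixed
#' linear-congruential step modulo a Mersenne prime, so derived seeds stay in
#' the 32-bit signed range and the scheme is stable across sessions and
#' platforms.
#'
#' @param master Integer master seed.
#' @param stage Character stage label (e.g. `"participant"`, `"replicate"`).
#' @param index Non-negative integer index within the stage.
#' @return A positive integer seed below 2^31.
#' @export
derive_seed <- function(master, stage, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.character(stage), length(stage) == 1L,
            is.numeric(index), length(index) == 1L, index >= 0)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 65521
  s <- (abs(as.double(master)) %% 2147483647) * 48271 + h * 9973 + as.double(index) * 7919
  as.integer(s %% 2147483629) + 1L
}

#' Latin Hypercube sample from a uniform exposure interval
#'
#' Draws `n` values from \eqn{U(a, b)} by stratified sampling: the unit
#' interval is split into `n` equal-probability strata, one uniform variate is
#' drawn inside each stratum, the strata are randomly permuted, and the
#' variates are mapped through the interval's inverse CDF. Exactly one sample
#' falls in each stratum, which pins the empirical CDF to the analytic CDF
#' within 1/n everywhere and sharply reduces the variance of the sample mean
#' relative to simple random sampling. Degenerate intervals return the point
#' value.
#'
#' @param lower,upper Scalar interval bounds, `0 <= lower <= upper`.
#' @param n Number of samples (>= 1).
#' @param seed Optional integer seed; when supplied the draw is made under a
#'   private Mersenne-Twister stream and the caller's RNG state is untouched.
#' @return Numeric vector of length `n` (in stratum-permuted order).
#' @examples
#' sort(lhs_sample(0, 1, 4, seed = 1))  # one sample per quartile stratum
#' @export
lhs_sample <- function(lower, upper, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) return(with_seed(seed, lhs_sample(lower, upper, n)))
  if (upper == lower) return(rep(lower, n))
  u <- (sample.int(n) - stats::runif(n)) / n
  lower + u * (upper - lower)
}

#' Simple random sample from a uniform exposure interval
#'
#' Unstratified counterpart of [lhs_sample()], retained behind the sampler
#' flag for variance-reduction comparisons.
#'
#' @inheritParams lhs_sample
#' @return Numeric vector of length `n`.
#' @export
srs_sample <- function(lower, upper, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) return(with_seed(seed, srs_sample(lower, upper, n)))
  if (upper == lower) return(rep(lower, n))
  stats::runif(n, lower, upper)
}

new_mc_distribution <- function(samples, sampler, seed) {
  structure(list(samples = as.numeric(samples),
                 n_trials = length(samples),
                 sampler = sampler,
                 seed = seed),
            class = "mc_distribution")
}

#' Participant-level Monte Carlo exposure distribution
#'
#' Samples one participant's uniform exposure interval `n_trials` times
#' (Latin Hypercube by default) and returns the empirical output distribution
#' of average weekly calls.
#'
#' @param interval A single-row `exposure_intervals` object (or list with
#'   `lower`/`upper`).
#' @param n_trials Number of Monte Carlo trials (default 1000).
#' @param seed Integer seed for the participant's private stream.
#' @param sampler `"lhs"` (default) or `"srs"`.
#' @return An `mc_distribution` object.
#' @export
mc_participant <- function(interval, n_trials = 1000, seed = 1L,
                           sampler = c("lhs", "srs")) {
  sampler <- match.arg(sampler)
  stopifnot(n_trials >= 1)
  a <- interval$lower[1]
  b <- interval$upper[1]
  draw <- if (sampler == "lhs") lhs_sample else srs_sample
  new_mc_distribution(draw(a, b, n_trials, seed = seed), sampler, seed)
}

#' Group-mean Monte Carlo distribution
#'
#' For each trial, one value is drawn from every participant's exposure
#' distribution and the across-participant mean is recorded; `n_trials`
#' repetitions give the output distribution of the group mean. Each
#' participant has an independent sampling stream derived from the master
#' seed, and under the LHS sampler each participant's `n_trials` draws are
#' themselves stratified.
#'
#' @param intervals An `exposure_intervals` object with one row per
#'   participant (at least one row).
#' @param n_trials Number of trials (default 1000).
#' @param seed Master integer seed; per-participant streams are derived via
#'   [derive_seed()].
#' @param sampler `"lhs"` (default) or `"srs"`.
#' @return An `mc_distribution` whose samples are the trial means.
#' @export
mc_group_mean <- function(intervals, n_trials = 1000, seed = 1L,
                          sampler = c("lhs", "srs")) {
  sampler <- match.arg(sampler)
  np <- nrow(intervals)
  if (is.null(np) || np < 1) stop("at least one exposure interval is required", call. = FALSE)
  stopifnot(n_trials >= 1)
  draw <- if (sampler == "lhs") lhs_sample else srs_sample
  draws <- vapply(seq_len(np), function(i) {
    draw(intervals$lower[i], intervals$upper[i], n_trials,
         seed = derive_seed(seed, "participant", i))
  }, numeric(n_trials))
  if (n_trials == 1L) draws <- matrix(draws, nrow = 1L)
  new_mc_distribution(rowMeans(draws), sampler, seed)
}

#' Summarise a Monte Carlo output distribution
#'
#' @param object An `mc_distribution`.
#' @param level Coverage of the percentile uncertainty interval, in (0, 1);
#'   default 0.95 gives the empirical 2.5th and 97.5th percentiles.
#' @param ... Unused.
#' @return A list with `mean`, `lower`, `upper`, `level`, `n_trials`, and
#'   `exceedance`, a function returning \eqn{1 - \hat F(t)} (the empirical
#'   probability of exceeding `t`).
#' @export
summary.mc_distribution <- function(object, level = 0.95, ...) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("level must be a single number strictly between 0 and 1", call. = FALSE)
  }
  if (length(object$samples) == 0L) stop("empty Monte Carlo sample", call. = FALSE)
  qs <- stats::quantile(object$samples, probs = c((1 - level) / 2, (1 + level) / 2),
                        names = FALSE)
  F_hat <- stats::ecdf(object$samples)
  structure(list(mean = mean(object$samples),
                 lower = qs[1], upper = qs[2], level = level,
                 n_trials = object$n_trials, sampler = object$sampler,
                 exceedance = function(t) 1 - F_hat(t)),
            class = "mc_summary")
}

#' @export
print.mc_summary <- function(x, ...) {
  cat(sprintf("Monte Carlo summary (%d %s trials)\n", x$n_trials, toupper(x$sampler)))
  cat(sprintf("  mean %.4f, %d%% interval [%.4f, %.4f]\n",
              x$mean, round(100 * x$level), x$lower, x$upper))
  invisible(x)
}

#' @export
print.mc_distribution <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("mc_distribution: %d %s trials, mean %.4f [%.4f, %.4f]\n",
              x$n_trials, toupper(x$sampler), s$mean, s$lower, s$upper))
  invisible(x)
}

#' Histogram export of a Monte Carlo distribution
#'
#' Bins the samples for plain-text export (histogram and cumulative curve),
#' mirroring the participant- and group-level output distribution figures.
#'
#' @param dist An `mc_distribution`.
#' @param breaks Number of bins or a vector of bin edges.
#' @return Data frame with `bin_lower`, `bin_upper`, `count`, `mass`,
#'   `cum_mass`.
#' @export
mc_histogram <- function(dist, breaks = 30) {
  h <- graphics::hist(dist$samples, breaks = breaks, plot = FALSE)
  data.frame(bin_lower = utils::head(h$breaks, -1),
             bin_upper = utils::tail(h$breaks, -1),
             count = h$counts,
             mass = h$counts / length(dist$samples),
             cum_mass = cumsum(h$counts) / length(dist$samples))
}
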