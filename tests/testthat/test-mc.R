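test_that("LHS places exactly one sample per probability stratum", {
  for (n in c(4, 10, 57)) {
    x <- lhs_sample(0, 1, n, seed = 101)
    expect_equal(sort(floor(x * n)), 0:(n - 1))
  }
})

test_that("degenerate intervals give point-mass samples", {
  expect_equal(lhs_sample(2, 2, 5, seed = 1), rep(2, 5))
  expect_equal(srs_sample(2, 2, 5, seed = 1), rep(2, 5))
  d <- mc_participant(exposure_intervals(2, 2), n_trials = 100, seed = 3)
  expect_equal(unique(d$samples), 2)
  s <- summary(d)
  expect_equal(c(s$mean, s$lower, s$upper), c(2, 2, 2))
})

test_that("LHS sample mean error is bounded by the stratum width", {
  x <- lhs_sample(1, 3, 1000, seed = 7)
  expect_lt(abs(mean(x) - 2), 0.004)
  y <- lhs_sample(0, 4, 1000, seed = 8)
  expect_lt(abs(mean(y) - 2), 0.002)
})

test_that("empirical CDF of an LHS run matches the analytic CDF within 1/n", {
  set.seed(202)
  for (n in c(10, 100, 1000)) {
    for (rep in 1:5) {
      a <- runif(1, 0, 3); b <- a + runif(1, 0.1, 5)
      x <- lhs_sample(a, b, n, seed = sample.int(1e6, 1))
      F_hat <- ecdf(x)
      for (t in seq(a, b, length.out = 11)) {
        expect_lte(abs(F_hat(t) - uniform_cdf(exposure_intervals(a, b), t)), 1 / n)
      }
    }
  }
})

test_that("participant-level MC reproduces the analytic classification probabilities", {
  d <- mc_participant(exposure_intervals(0, 4), n_trials = 1000, seed = 5)
  p <- mean(d$samples <= 2)
  expect_gte(p, 0.499); expect_lte(p, 0.501)
  # an interval with > 80% analytic probability of averaging below 2 calls
  d2 <- mc_participant(exposure_intervals(0.5, 2.25), n_trials = 1000, seed = 6)
  expect_gt(mean(d2$samples < 2), 0.8)
})

test_that("MC-based classification agrees with the analytic rule away from the boundary", {
  set.seed(77)
  n <- 1000
  for (i in 1:50) {
    m <- runif(1, 0.1, 5); h <- runif(1, 0.05, 0.9) * m
    iv <- exposure_intervals(m - h, m + h)
    p <- uniform_cdf(iv, 2)
    if (abs(p - 0.5) <= 2 / n) next
    d <- mc_participant(iv, n_trials = n, seed = i)
    expect_equal(mean(d$samples <= 2) >= 0.5, p >= 0.5)
  }
})

test_that("group-mean MC has the closed-form mean and trial variance", {
  iv <- exposure_intervals(c(2, 2), c(2, 2))
  d <- mc_group_mean(iv, n_trials = 50, seed = 4)
  expect_equal(unique(d$samples), 2)

  iv2 <- exposure_intervals(c(0, 2), c(2, 4))
  d2 <- mc_group_mean(iv2, n_trials = 2000, seed = 9)
  expect_lt(abs(mean(d2$samples) - 2), 0.01)
  # var of the mean of two independent U(.,.) widths 2: (4/12 + 4/12)/4
  expect_lt(abs(var(d2$samples) - 1 / 6), 0.1 / 6)
})

test_that("group-mean MC requires at least one interval", {
  expect_error(mc_group_mean(exposure_intervals(numeric(0), numeric(0))),
               "at least one")
})

test_that("LHS strictly reduces the variance of the sample mean versus SRS", {
  seeds <- 1:100
  lhs_means <- vapply(seeds, function(s) mean(lhs_sample(1, 3, 100, seed = s)), 1)
  srs_means <- vapply(seeds, function(s) mean(srs_sample(1, 3, 100, seed = s)), 1)
  expect_lt(var(lhs_means), var(srs_means))
})

test_that("identical seeds reproduce identical samples and leave the global RNG alone", {
  iv <- exposure_intervals(c(0.5, 1), c(2, 6))
  d1 <- mc_group_mean(iv, n_trials = 200, seed = 123)
  d2 <- mc_group_mean(iv, n_trials = 200, seed = 123)
  expect_identical(d1$samples, d2$samples)
  set.seed(55); before <- runif(5)
  set.seed(55); invisible(mc_group_mean(iv, n_trials = 50, seed = 9)); after <- runif(5)
  expect_identical(before, after)
})

test_that("summaries use empirical percentiles and validate the level", {
  s <- summary(new_dist <- structure(list(samples = c(1, 2, 3, 4), n_trials = 4L,
                                          sampler = "lhs", seed = 1L),
                                     class = "mc_distribution"), level = 0.5)
  # middle half of the sorted sample: hand-computed type-7 quartiles
  expect_equal(c(s$lower, s$upper), c(1.75, 3.25))
  expect_equal(s$exceedance(2), 0.5)
  expect_error(summary(new_dist, level = 1.2), "between 0 and 1")
})

test_that("derived seeds are deterministic, distinct across streams, and 32-bit safe", {
  expect_identical(derive_seed(42, "participant", 7), derive_seed(42, "participant", 7))
  s <- c(derive_seed(42, "participant", 1), derive_seed(42, "participant", 2),
         derive_seed(42, "replicate", 1), derive_seed(43, "participant", 1))
  expect_equal(anyDuplicated(s), 0L)
  expect_true(all(s > 0 & s < 2^31))
})

test_that("histogram export conserves probability mass", {
  d <- mc_participant(exposure_intervals(1, 3), n_trials = 500, seed = 2)
  h <- mc_histogram(d, breaks = 12)
  expect_equal(sum(h$mass), 1)
  expect_equal(max(h$cum_mass), 1)
  expect_true(all(diff(h$cum_mass) >= 0))
})
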