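test_that("speed transform is base-10 log with domain checks", {
  expect_equal(transform_speed(1000), 3)
  expect_equal(transform_speed(1), 0)
  expect_equal(transform_speed(632), 2.80072, tolerance = 1e-5)
  expect_error(transform_speed(0), "positive")
  expect_error(transform_speed(NA), "NA")
})

test_that("accuracy transform is arcsine square root on proportions", {
  expect_equal(transform_accuracy(0), 0)
  expect_equal(transform_accuracy(1), pi / 2)
  expect_equal(transform_accuracy(0.5), pi / 4)
  expect_error(transform_accuracy(1.5), "proportion")
  expect_error(transform_accuracy(-0.1), "proportion")
})

test_that("Stroop interference ratio compares matched forms", {
  expect_equal(stroop_ratio(10, 11), 0.1)
  expect_equal(stroop_ratio(10, 10), 0)
  expect_equal(stroop_ratio(100, 109), 0.09)
  expect_error(stroop_ratio(0, 5), "positive")
})

test_that("transforms are strictly increasing and invertible on interior points", {
  x <- seq(10, 2000, length.out = 50)
  expect_true(all(diff(transform_speed(x)) > 0))
  expect_equal(inverse_speed(transform_speed(x)), x, tolerance = 1e-12)
  p <- seq(0.01, 0.99, length.out = 50)
  expect_true(all(diff(transform_accuracy(p)) > 0))
  expect_equal(inverse_accuracy(transform_accuracy(p)), p, tolerance = 1e-12)
})

test_that("cohort-level transformation maps raw columns onto the analysis scale", {
  raw <- data.frame(
    participant_id = c("a", "b"), school_id = c("S1", "S2"),
    baseline_calls = c(0, 1), followup_calls = c(0, 3),
    go_nogo_speed_baseline = c(632, 500), go_nogo_speed_followup = c(578, 400),
    go_nogo_accuracy_baseline = c(96, 50), go_nogo_accuracy_followup = c(98, 75),
    groton_maze_errors_baseline = c(69, 40), groton_maze_errors_followup = c(56, 30)
  )
  attr(raw, "scale") <- "raw"
  tr <- transform_cohort(raw)
  expect_equal(tr$go_nogo_speed_baseline, log10(c(632, 500)))
  expect_equal(tr$go_nogo_accuracy_followup, asin(sqrt(c(0.98, 0.75))))
  expect_equal(tr$groton_maze_errors_followup, c(56, 30))
  expect_identical(attr(tr, "scale"), "transformed")
  # idempotent on already transformed cohorts
  expect_identical(transform_cohort(tr), tr)
})
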