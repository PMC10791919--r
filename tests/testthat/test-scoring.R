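test_that("mean RT uses the median-six rule", {
  expect_equal(mean_rt(fake_trials(1:20, rt = 400))$outcome, 400)
  tr <- fake_trials(rep(1, 20), rt = 1)
  tr$rt_ms <- 20:1   # order must not matter
  expect_equal(mean_rt(tr)$outcome, mean(8:13))   # 10.5
  # correct-only filtering: 3 errors leave 17, middle six are ranks 6..11
  tr <- fake_trials(rep(1, 20), rt = 1)
  tr$rt_ms <- 1:20
  tr$correct <- rep(TRUE, 20)
  tr$correct[c(1, 2, 3)] <- FALSE
  left <- sort((1:20)[-(1:3)])
  expect_equal(mean_rt(tr, correct_only = TRUE)$outcome, mean(left[6:11]))
  expect_equal(mean_rt(tr, correct_only = TRUE)$n_trials_used, 17)
  # fewer than six usable values: average all and flag
  short <- fake_trials(rep(1, 4), rt = 1); short$rt_ms <- c(10, 20, 30, 40)
  r <- mean_rt(short)
  expect_equal(r$outcome, 25)
  expect_true(r$flagged)
  none <- fake_trials(rep(1, 3), correct = FALSE)
  expect_error(mean_rt(none, correct_only = TRUE), "no usable")
})

test_that("staircase threshold is the mean of the final five levels", {
  tr <- fake_trials(c(rep(20, 19), 12, 12, 12, 12, 12))
  expect_equal(staircase_threshold(tr), 12)
  tr <- fake_trials(c(rep(20, 19), 10, 11, 10, 11, 10))
  expect_equal(staircase_threshold(tr), 10.4)
  expect_equal(staircase_threshold(tr, k = 1), 10)   # degenerate k
  expect_error(staircase_threshold(fake_trials(1:3)), "at least")
  # pure function of (trial, level): row order is irrelevant
  shuf <- tr[sample(nrow(tr)), ]
  expect_equal(staircase_threshold(shuf), 10.4)
})

test_that("dynamic threshold averages uncensored ramp amplitudes", {
  tr <- fake_trials(rep(15.6, 7), protocol = "DDT")
  expect_equal(dynamic_threshold(tr)$outcome, 15.6)
  tr <- fake_trials(c(14, 15, 16, 15, 14, 16, 15), protocol = "DDT")
  expect_equal(dynamic_threshold(tr)$outcome, 15)
  tr$censored[7] <- TRUE
  expect_warning(dynamic_threshold(tr), "censored")
  r <- suppressWarnings(dynamic_threshold(tr))
  expect_equal(r$outcome, mean(c(14, 15, 16, 15, 14, 16)))
  expect_true(r$flagged)
  tr$censored <- TRUE
  expect_error(dynamic_threshold(tr), "censored")
})

test_that("percent change follows the printed orientation per pair", {
  expect_equal(percent_change(7, 7, "SDT_DDT"), 0)
  expect_equal(percent_change(10, 25, "SDT_DDT"), 150)
  expect_equal(percent_change(4, 6, "SQFD_SMFD"), 50)
  expect_equal(percent_change(40, 60, "TOJ_TOJwc"), 50)
  # the amplitude pair's printed formula inverts the ratio
  expect_equal(percent_change(20, 40, "ADT_ADTssa"), -50)
  expect_equal(percent_change(20, 40, "ADT_ADTssa",
                              consistent_orientation = TRUE), 100)
  expect_error(percent_change(0, 10, "SDT_DDT"), "denominator")
  expect_error(percent_change(1, 2, "NOPE"), "unknown pair")
  # scale invariance
  set.seed(5)
  for (i in 1:20) {
    a <- runif(1, 1, 50); b <- runif(1, 1, 50); c <- runif(1, 0.1, 10)
    expect_equal(percent_change(a, b, "SDT_DDT"),
                 percent_change(c * a, c * b, "SDT_DDT"))
  }
})

test_that("MAD filter removes gross outliers and keeps constant vectors", {
  expect_warning(keep <- mad_outlier_filter(c(5, 5, 5, 5)), "MAD is zero")
  expect_true(all(keep))
  keep <- mad_outlier_filter(c(1, 2, 3, 4, 100))
  expect_equal(keep, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_error(mad_outlier_filter(c(1, 2)), "at least 3")
  # translation/scale equivariance of the mask
  set.seed(6)
  x <- rnorm(50)
  for (i in 1:10) {
    a <- runif(1, -5, 5); if (abs(a) < 0.1) a <- 1
    b <- runif(1, -100, 100)
    expect_identical(mad_outlier_filter(x), mad_outlier_filter(a * x + b))
  }
})

test_that("MAD removal fraction on Gaussian data matches the normal tail", {
  set.seed(8)
  x <- rnorm(2e5)
  frac <- mean(!mad_outlier_filter(x))
  expect_equal(frac, 2 * pnorm(-2.5), tolerance = 0.15)  # ~1.24%
})

test_that("score_battery extracts the right outcome per protocol", {
  cg <- generate_cohort(effect_spec(), c(1, 1, 1, 1), seed = 61L)
  tr <- run_battery(cg$params[1:2, ], seed = 62L)
  out <- score_battery(tr)
  expect_equal(nrow(out), 2 * 10)
  expect_equal(out$outcome_kind[out$protocol == "SRT"][1], "mean_rt")
  expect_equal(out$outcome_kind[out$protocol == "SDT"][1],
               "static_threshold")
  expect_equal(out$outcome_kind[out$protocol == "DDT"][1],
               "dynamic_threshold")
  expect_equal(out$unit[out$protocol == "SQFD"][1], "Hz")
  expect_equal(out$unit[out$protocol == "TOJ"][1], "ms")
  expect_true(all(out$outcome > 0))
  idx <- derive_indices(out)
  expect_equal(sort(unique(idx$pair_id)),
               c("ADT_ADTssa", "SDT_DDT", "SQFD_SMFD", "TOJ_TOJwc"))
  expect_equal(nrow(idx), 2 * 4)
  # the detection index reproduces percent_change on the member outcomes
  one <- idx[idx$pair_id == "SDT_DDT" & idx$observer_id ==
               out$observer_id[1], ]
  expect_equal(one$percent_change,
               percent_change(one$first, one$second, "SDT_DDT"))
})

test_that("outlier flagging respects its grouping level", {
  outcomes <- data.frame(
    observer_id = sprintf("O%02d", 1:12),
    protocol = "SDT", outcome_kind = "static_threshold",
    outcome = c(10, 11, 10, 11, 10, 12, 11, 10, 11, 10, 11, 60),
    unit = "um", n_trials_used = 24L, flagged_scoring = FALSE,
    flagged_outlier = FALSE, stringsAsFactors = FALSE)
  cohort <- data.frame(observer_id = outcomes$observer_id,
                       diagnosis = rep(c("ASC", "TDC"), each = 6),
                       sex = rep(c("M", "M", "M", "F", "F", "F"), 2),
                       stringsAsFactors = FALSE)
  glob <- flag_outliers(outcomes, grouping = "protocol")
  expect_true(glob$flagged_outlier[12])
  expect_equal(sum(glob$flagged_outlier), 1)
  by_cell <- flag_outliers(outcomes, cohort, grouping = "cell")
  expect_true(by_cell$flagged_outlier[12])
  expect_error(flag_outliers(outcomes, grouping = "cell"), "cohort")
})
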