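test_that("rhythmicity test detects a clean 24-h cosine", {
  tt <- make_times()
  y <- make_cosine(tt$time_h, noise_sd = 0.05, seed = 3)
  rt <- rhythmicity_test(y, tt$time_h, n_permutations = 499, seed = 1)
  expect_lt(rt$p_value, 0.01)
  expect_equal(rt$amplitude, 0.5, tolerance = 0.1)
  # fitted peak lands near the construction's 22:00 peak
  peak_clock <- (6 + rt$peak_h) %% 24
  expect_lt(min(abs(peak_clock - 22), 24 - abs(peak_clock - 22)), 2)
})

test_that("rhythmicity test does not reject on constant series", {
  tt <- make_times()
  rt <- rhythmicity_test(rep(3.7, length(tt$time_h)), tt$time_h,
                         n_permutations = 199, seed = 2)
  expect_gt(rt$p_value, 0.05)
})

test_that("destroying the time order destroys the detected rhythm", {
  tt <- make_times()
  y <- make_cosine(tt$time_h, noise_sd = 0.05, seed = 4)
  rejections <- dielphage:::with_seed(11, {
    vapply(1:100, function(i) {
      rhythmicity_test(sample(y), tt$time_h, n_permutations = 199,
                       seed = i)$p_value <= 0.05
    }, logical(1))
  })
  expect_gte(mean(!rejections), 0.90)
})

test_that("rhythmicity test refuses series with insufficient coverage", {
  short <- make_times(n_days = 1.5)
  expect_error(rhythmicity_test(rnorm(length(short$time_h)), short$time_h),
               "insufficient coverage")
  sparse <- seq(0, 72, by = 12)  # 3 periods but only 2 samples per period
  expect_error(rhythmicity_test(rnorm(length(sparse)), sparse),
               "insufficient coverage")
})

test_that("day-night ratio recovers constructed contrasts", {
  tt <- make_times(n_days = 3)
  w <- diel_windows()
  night <- dielphage:::in_clock_window(tt$clock_h, w$night)
  y <- ifelse(night, 4, 2)
  expect_equal(day_night_ratio(y, tt$clock_h, w)$ratio, 2.0)
  expect_equal(day_night_ratio(rep(5, length(tt$clock_h)), tt$clock_h, w)$ratio, 1.0)
  # invariance to rescaling the whole series
  expect_equal(day_night_ratio(7.3 * y, tt$clock_h, w)$ratio, 2.0)
})

test_that("day-night ratio names the empty window in its error", {
  w <- diel_windows()
  expect_error(day_night_ratio(c(1, 2), c(7, 10), w), "night window")
  expect_error(day_night_ratio(c(1, 2), c(19, 23), w), "day window")
})

test_that("clock windows are half-open and wrap midnight", {
  w <- diel_windows()
  expect_true(dielphage:::in_clock_window(18, w$night))   # start included
  expect_true(dielphage:::in_clock_window(1.99, w$night)) # wraps past 00:00
  expect_false(dielphage:::in_clock_window(2, w$night))   # end excluded
  expect_false(dielphage:::in_clock_window(14, w$day))
  expect_error(diel_windows(night = c(18, 2), day = c(1, 9)), "overlap")
})

test_that("nightly budget closes the production-loss identity", {
  tt <- make_times(n_days = 2)
  # flat 2e5 pre-dusk, rising to a 2.4e5 post-dusk peak
  host <- rep(2e5, length(tt$time_h))
  host[tt$clock_h == 22] <- 2.3e5
  host[tt$clock_h == 2] <- 2.4e5
  b <- nightly_budget(host, tt$time_h, tt$clock_h, division_fraction = 1)
  expect_equal(b$expected[1], 2e5)
  expect_equal(b$observed[1], 0.4e5)
  expect_equal(b$implied_loss[1], 1.6e5)
  # conservation identity, exact
  expect_identical(b$expected, b$observed + b$implied_loss)
  # observed equal to expected implies zero loss
  host2 <- rep(1.6e5, length(tt$time_h))
  host2[tt$clock_h %in% c(22, 2)] <- 3.2e5
  b2 <- nightly_budget(host2, tt$time_h, tt$clock_h, division_fraction = 1)
  expect_equal(b2$implied_loss[1], 0)
})

test_that("nightly budget requires a dusk anchor", {
  expect_error(nightly_budget(c(1e5, 1.1e5), c(0, 4), c(20, 0)),
               "dusk anchor")
})

test_that("infected-cell concentrations follow from percent and abundance", {
  expect_equal(infected_cells_per_ml(0.35, 1.49e5), 521.5)
  expect_equal(infected_cells_per_ml(0, 1e9), 0)
  expect_equal(infected_cells_per_ml(1.0, 1e5), 1000)
  expect_error(infected_cells_per_ml(-1, 1e5), "non-negative")
})

test_that("sample series validates timestamps and concentrations", {
  tt <- make_times(n_days = 1)
  expect_error(sample_series(rev(tt$timestamp), 1e5, 3e5, 2e4),
               "strictly increasing")
  expect_error(sample_series(tt$timestamp, -1, 3e5, 2e4), "non-negative")
  s <- sample_series(tt$timestamp, 1.5e5, 3e5, 2e4, infected_percent = 1)
  expect_equal(s$infected_per_ml, rep(1500, nrow(s)))
  expect_equal(s$clock_h[1], 6)
})
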