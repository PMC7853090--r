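test_that("diffusive encounter kernel follows beta = 2 pi d D", {
  expect_equal(encounter_kernel(1, 1e-7), 2 * pi * 1e-4 * 1e-7)
  expect_equal(encounter_kernel(2, 1e-7), 2 * encounter_kernel(1, 1e-7))
})

test_that("kernel calibration inverts the per-cell encounter rate", {
  beta <- calibrate_beta(54, 3.3e5)
  expect_equal(beta, 1 / (54 * 3600 * 3.3e5))
  expect_equal(signif(beta, 3), 1.56e-11)
  # round trip to machine precision
  expect_equal(per_cell_encounter_rate(beta, 3.3e5)$interval_h, 54)
})

test_that("per-cell encounter rate handles zero concentration and scales", {
  beta <- calibrate_beta(54, 3.3e5)
  zero <- per_cell_encounter_rate(beta, 0)
  expect_equal(zero$rate_per_day, 0)
  expect_identical(zero$interval_h, Inf)
  expect_equal(per_cell_encounter_rate(beta, 2 * 3.3e5)$interval_h, 27)
})

test_that("population encounters and the mortality ceiling compose", {
  beta <- calibrate_beta(54, 3.3e5)
  rate <- per_cell_encounter_rate(beta, 3.3e5)$rate_per_day
  enc <- population_daily_encounters(rate, 1.6e5)
  expect_equal(enc, 24 / 54 * 1.6e5)
  expect_equal(report_encounters(enc), 70000)
  expect_equal(population_daily_encounters(0, 1e5), 0)
  expect_equal(population_daily_encounters(1, 1000), 1000)
  expect_equal(max_daily_mortality(70000, 1.6e5), 43.75)
  expect_equal(max_daily_mortality(0, 1e5), 0)
  expect_equal(max_daily_mortality(1e5, 1e5), 100)
  expect_equal(max_daily_mortality(2e5, 1e5), 100)  # capped
})

test_that("cycles per day clamp the latent-period quotient", {
  c79 <- cycles_per_day(7.9)
  expect_equal(c79$raw, 24 / 7.9)
  expect_equal(c79$clamped, 3L)
  expect_equal(cycles_per_day(24)$clamped, 1L)
  expect_equal(cycles_per_day(12)$clamped, 2L)
  expect_equal(cycles_per_day(30)$clamped, 1L)  # clamp floor
  expect_equal(cycles_per_day(2)$clamped, 3L)   # clamp ceiling
})

test_that("daily mortality bounds pair extremes of infection and cycles", {
  b <- daily_mortality_bounds(mortality_model())
  expect_equal(b[["low"]], 0.35)
  expect_equal(b[["high"]], 4.8)
  expect_equal(daily_mortality_bounds(
    mortality_model(instantaneous_range = c(0, 0)))[["high"]], 0)
  # low <= high for random valid models
  set.seed(8)
  for (i in 1:30) {
    r <- sort(runif(2, 0, 3))
    cyc <- sort(sample(1:5, 2, replace = TRUE))
    b <- daily_mortality_bounds(mortality_model(cycles_range = cyc,
                                                instantaneous_range = r))
    expect_lte(b[["low"]], b[["high"]])
  }
})

test_that("fraction of infective encounters maps mortality to encounters", {
  expect_equal(fraction_encounters_infective(560, 70000), 0.8)
  expect_equal(signif(fraction_encounters_infective(7680, 70000), 2), 11)
  expect_equal(fraction_encounters_infective(70000, 70000), 100)
  expect_error(fraction_encounters_infective(10, 0), "positive")
  # monotone in the mortality bound
  lows <- fraction_encounters_infective(560, 70000)
  highs <- fraction_encounters_infective(7680, 70000)
  expect_lt(lows, highs)
})

test_that("phage turnover time satisfies its conservation identity", {
  slow <- turnover_model(cycles_per_day = 1)
  fast <- turnover_model(cycles_per_day = 3)
  expect_equal(report_days(phage_turnover_time(slow)), 23)
  expect_equal(report_days(phage_turnover_time(fast)), 8)
  # doubling burst size halves turnover time
  double <- turnover_model(burst_size = 24, cycles_per_day = 1)
  expect_equal(phage_turnover_time(double), phage_turnover_time(slow) / 2)
  # conservation: turnover x daily production = standing stock, exactly
  for (m in list(slow, fast, double)) {
    expect_identical(
      phage_turnover_time(m) * m$burst_size * m$lysed_per_cycle * m$cycles_per_day,
      m$standing_stock)
  }
})

test_that("required burst size is the phage-to-infected increase ratio", {
  expect_equal(required_burst_size(76000, 500), 152)
  expect_equal(report_burst(required_burst_size(76000, 500)), 150)
  expect_equal(required_burst_size(0, 500), 0)
  expect_equal(required_burst_size(14400, 1200), 12)
  expect_error(required_burst_size(100, 0), "positive")
})

test_that("mechanism reconciliation splits the encounter-infection gap", {
  r <- reconcile_mechanisms(3010, 70000, 1.6e5)
  expect_equal(r$f_susceptible, 4.3)
  expect_equal(r$f_infectious, r$f_adsorb)
  expect_equal(round(r$f_resistant), 96)
  expect_equal(r$resistant_per_ml, (1 - 3010 / 70000) * 1.6e5)
  all100 <- reconcile_mechanisms(70000, 70000, 1e5)
  expect_equal(all100$f_susceptible, 100)
  expect_equal(all100$f_resistant, 0)
  combined <- reconcile_mechanisms(0.027 * 70000, 70000, 1e5)
  expect_equal(combined$combined_balanced, 100 * 0.027^(1 / 3))
  expect_equal(round(combined$combined_balanced), 30)
  expect_warning(reconcile_mechanisms(2, 1, 1), "exceeds")
})

test_that("dimensionless outputs are invariant to per-litre concentrations", {
  # express all concentrations per litre (x1000): percents and folds unchanged
  expect_equal(max_daily_mortality(70000 * 1000, 1.6e5 * 1000),
               max_daily_mortality(70000, 1.6e5))
  expect_equal(fraction_encounters_infective(560 * 1000, 70000 * 1000),
               fraction_encounters_infective(560, 70000))
  expect_equal(required_burst_size(76000 * 1000, 500 * 1000),
               required_burst_size(76000, 500))
  r1 <- reconcile_mechanisms(3010, 70000, 1.6e5)
  r2 <- reconcile_mechanisms(3010e3, 70000e3, 1.6e8)
  expect_equal(r1$f_susceptible, r2$f_susceptible)
  expect_equal(r1$combined_balanced, r2$combined_balanced)
  m1 <- turnover_model(standing_stock = 3.3e5, lysed_per_cycle = 1200)
  m2 <- turnover_model(standing_stock = 3.3e8, lysed_per_cycle = 1.2e6)
  expect_equal(phage_turnover_time(m1), phage_turnover_time(m2))
})
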