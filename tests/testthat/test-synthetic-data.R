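test_that("campaign generation is byte-identical under one seed", {
  cfg <- sim_config(seed = 101)
  a <- generate_campaign(cfg)
  b <- generate_campaign(cfg)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  readr::write_csv(a$truth, f1)
  readr::write_csv(b$truth, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(a$series, b$series)
  gels1 <- simulate_campaign_assays(a, cfg)
  gels2 <- simulate_campaign_assays(b, cfg)
  expect_identical(gels1, gels2)
  # a different seed changes the draw
  expect_false(identical(a$truth$true_fraction,
                         generate_campaign(sim_config(seed = 102))$truth$true_fraction))
})

test_that("a null campaign produces zero infection and zero polonies", {
  cfg <- sim_config(seed = 5, infection_mean_percent = 0)
  camp <- generate_campaign(cfg)
  expect_true(all(camp$truth$true_fraction == 0))
  gels <- simulate_campaign_assays(camp, cfg)
  expect_true(all(gels$polony_count == 0))
})

test_that("default campaign hits the target mean infected fraction", {
  camp <- generate_campaign(sim_config(seed = 42))
  mean_pct <- 100 * mean(camp$truth$true_fraction)
  expect_gte(mean_pct, 0.70)
  expect_lte(mean_pct, 0.88)
  # stage occupancies always sum to 1 and host/phage stay in their ranges
  occ <- camp$truth$occ_pre + camp$truth$occ_during + camp$truth$occ_post
  expect_equal(occ, rep(1, nrow(camp$truth)))
  expect_true(all(camp$truth$phage_T4 >= 2.7e5 & camp$truth$phage_T4 <= 4.1e5))
  expect_true(all(camp$truth$phage_T7 >= 1.7e4 & camp$truth$phage_T7 <= 3.8e4))
})

test_that("the generator's periodic and aperiodic channels separate", {
  camp <- generate_campaign(sim_config(seed = 42))
  p_inf <- rhythmicity_test(camp$truth$true_fraction, camp$truth$time_h,
                            n_permutations = 499, seed = 1)$p_value
  p_t4 <- rhythmicity_test(camp$truth$phage_T4, camp$truth$time_h,
                           n_permutations = 499, seed = 2)$p_value
  expect_lt(p_inf, 0.01)
  expect_gt(p_t4, 0.05)
})

test_that("assay simulation obeys the thinning expectation", {
  # perfect detection: expected polonies = cells x fraction
  cfg1 <- sim_config(seed = 9, efficiency = efficiency_model(c(1, 1, 1)),
                     cells_per_gel = c(10000, 10000), gels_per_sample = 1)
  counts <- vapply(1:300, function(i) {
    simulate_assay(0.01, rep(1, 3) / 3, cfg1, seed = i)$polony_count
  }, numeric(1))
  se <- sqrt(10000 * 0.01 * 0.99 / 300)
  expect_lt(abs(mean(counts) - 100), 3 * se)

  # stage-dependent thinning: all post-replication at efficiency 0.86
  cfg2 <- sim_config(seed = 9, cells_per_gel = c(10000, 10000),
                     gels_per_sample = 1)
  counts2 <- vapply(1:300, function(i) {
    simulate_assay(0.01, c(0, 0, 1), cfg2, seed = i)$polony_count
  }, numeric(1))
  se2 <- sqrt(10000 * 0.01 * 0.86 / 300)  # binomial-thinned variance bound
  expect_lt(abs(mean(counts2) - 86), 3 * se2)

  # mixed stages: expectation = cells x fraction x sum(occ x eff)
  occ <- c(0.5, 0.3, 0.2)
  eexp <- 10000 * 0.01 * sum(occ * c(0.25, 0.55, 0.86))
  counts3 <- vapply(1:300, function(i) {
    simulate_assay(0.01, occ, cfg2, seed = 1000 + i)$polony_count
  }, numeric(1))
  expect_lt(abs(mean(counts3) - eexp), 3 * sqrt(eexp / 300))
})

test_that("co-sorting contributes Poisson false polonies that subtract out", {
  cfg <- sim_config(seed = 3, cosort_rate = 3, cells_per_gel = c(10000, 10000),
                    gels_per_sample = 1)
  draws <- t(vapply(1:1000, function(i) {
    g <- simulate_assay(0, rep(1, 3) / 3, cfg, seed = i)
    c(g$polony_count, g$filtrate_polony_count)
  }, numeric(2)))
  # with zero infection both gel and filtrate counts are Poisson(cosort_rate)
  expect_equal(mean(draws[, 1]), 3, tolerance = 0.2)
  expect_equal(mean(draws[, 2]), 3, tolerance = 0.2)
  expect_equal(var(draws[, 1]), 3, tolerance = 0.5)
  corrected <- correct_cosort_empirical(draws[, 1], draws[, 2])
  # empirical subtraction is unbiased up to the clip at zero
  expect_lt(mean(corrected) - mean(pmax(draws[, 1] - draws[, 2], 0)), 1e-12)
  expect_lt(abs(mean(draws[, 1] - draws[, 2])), 3 * sqrt(6 / 1000))
})

test_that("the truth channel never leaks into the emitted series", {
  camp <- generate_campaign(sim_config(seed = 17))
  leaked <- grep("true|occ_", names(camp$series), value = TRUE)
  expect_length(leaked, 0)
  gels <- simulate_campaign_assays(camp, sim_config(seed = 17))
  expect_false("true_infected" %in% names(gels))
})

test_that("sim_config validates ranges and requires a seed", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(seed = 1, cells_per_gel = c(10000, 8000)), "ordered")
  expect_error(sim_config(seed = 1, host_amplitude = 2e5), "host_amplitude")
  expect_error(sim_config(seed = 1, infection_mean_percent = -1), "outside")
})

test_that("identity pipeline recovers truth up to counting noise", {
  cfg <- sim_config(seed = 21, efficiency = efficiency_model(c(1, 1, 1)),
                    cosort_rate = 0, infection_noise_cv = 0,
                    stage_phasing = 0)
  rec <- end_to_end_recovery(cfg, bootstrap = bootstrap_config(
    iterations = 300, seed = 1, count_resampling = "none"))
  # with perfect detection the adjusted estimate equals the raw pooled ratio
  expect_equal(rec$per_sample$percent_adjusted, rec$per_sample$percent_raw)
  expect_equal(rec$mean_recovered_percent, rec$mean_true_percent,
               tolerance = 0.05)
})
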