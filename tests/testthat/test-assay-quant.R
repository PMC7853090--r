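test_that("raw percent infection divides polonies by input cells", {
  expect_equal(raw_percent_infection(5, 10000), 0.05)   # the assay's LOD
  expect_equal(raw_percent_infection(0, 10000), 0)
  expect_equal(raw_percent_infection(152, 8000), 1.9)
  expect_error(raw_percent_infection(5, 0), "positive")
  expect_error(raw_percent_infection(5, -10), "positive")
})

test_that("raw percent infection is linear in the polony count", {
  counts <- 0:50
  p <- raw_percent_infection(counts, 8000)
  expect_equal(p, counts * raw_percent_infection(1, 8000))
})

test_that("empirical co-sort subtraction clips at zero and needs a control", {
  expect_equal(correct_cosort_empirical(100, 10), 90)
  expect_equal(correct_cosort_empirical(10, 10), 0)
  expect_equal(correct_cosort_empirical(5, 0), 5)
  expect_error(correct_cosort_empirical(10, NA), "control unavailable")
  # property: 0 <= corrected <= polony_count for arbitrary counts
  set.seed(41)
  p <- rpois(500, 20)
  f <- rpois(500, 20)
  corrected <- correct_cosort_empirical(p, f)
  expect_true(all(corrected >= 0))
  expect_true(all(corrected <= p))
})

test_that("factor co-sort correction applies only above the family threshold", {
  expect_equal(correct_cosort_factor(1.00, "T4like", 4e5), 0.805)
  expect_equal(correct_cosort_factor(1.00, "T4like", 1e5), 1.00)
  expect_equal(correct_cosort_factor(2.00, "T7like", 6e5), 1.836)
  expect_equal(correct_cosort_factor(2.00, "T7like", 4e5), 2.00)
  expect_error(correct_cosort_factor(1, "lambda", 1e5), "unknown phage family")
  # never increases percent, for either family and any concentration
  set.seed(42)
  pc <- runif(200, 0, 5)
  conc <- 10^runif(200, 3, 7)
  fam <- sample(c("T4like", "T7like"), 200, replace = TRUE)
  expect_true(all(correct_cosort_factor(pc, fam, conc) <= pc))
})

test_that("gel QC classifies counts against the 5-2000 polony bounds", {
  expect_equal(qc_gel(4), "below_loq")
  expect_equal(qc_gel(2001), "saturated")
  expect_equal(qc_gel(500), "ok")
  expect_equal(qc_gel(c(5, 2000)), c("ok", "ok"))  # bounds are inclusive
  custom <- gel_qc_policy(min_polonies = 10, max_polonies = 100)
  expect_equal(qc_gel(9, custom), "below_loq")
  expect_error(gel_qc_policy(0, 100), "min_polonies")
})

test_that("replicate pooling is count-pooled, not mean-of-percents", {
  gels <- make_gels(c(50, 60), c(10000, 10000))
  pooled <- pool_replicates(gels)
  expect_equal(pooled$percent, 0.55)
  expect_equal(pooled$per_gel, c(0.5, 0.6))
  # unequal cell loads: pooling weights by cells screened
  gels2 <- make_gels(c(10, 100), c(1000, 100000))
  expect_equal(pool_replicates(gels2)$percent, 100 * 110 / 101000)
})

test_that("pooling a single gel equals its raw percent infection", {
  gels <- make_gels(5, 10000)
  pooled <- pool_replicates(gels)
  expect_equal(pooled$percent, raw_percent_infection(5, 10000))
  expect_equal(pooled$qc_status, "ok")
})

test_that("samples whose gels all fail low are censored at the LOD, not dropped", {
  gels <- make_gels(c(0, 0), c(10000, 10000))
  pooled <- pool_replicates(gels)
  expect_equal(pooled$percent, 0)
  expect_equal(pooled$qc_status, "below_loq")
  expect_true(pooled$censored)
  expect_equal(pooled$lod_percent, 100 * 5 / 20000)
})

test_that("pooling excludes failing gels when at least one passes", {
  gels <- make_gels(c(3, 60), c(10000, 10000))
  pooled <- pool_replicates(gels)
  expect_equal(pooled$percent, 0.6)
  expect_false(pooled$censored)
})

test_that("pooling errors on empty or unquantifiable input", {
  expect_error(pool_replicates(make_gels(numeric(0), numeric(0))),
               "missing|empty|no quantifiable")
  expect_error(pool_replicates(make_gels(c(3000, 4000), c(10000, 10000))),
               "no quantifiable gel")
  mixed <- dplyr::bind_rows(make_gels(50, 10000, sample_id = "a"),
                            make_gels(50, 10000, sample_id = "b"))
  expect_error(pool_replicates(mixed), "one sample")
})

test_that("gel table validation rejects unphysical records", {
  expect_error(gel_assay(-1, 10000), "non-negative")
  expect_error(gel_assay(10, 10000, filtrate_polony_count = -1), "non-negative")
  expect_error(gel_assay(10, 10000, phage_family = "unknown"), "phage family")
})
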