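## Synthetic diel campaign generator with a ground-truth channel.
##
## Emulates a Lagrangian field campaign in oligotrophic subtropical surface
## waters: 4-hourly sampling over 7 diel cycles; Prochlorococcus at
## 1.2-2.3e5 cells per ml oscillating with synchronous dusk division and a
## pre-dawn loss pulse; aperiodic T4-like (2.7-4.1e5 per ml) and T7-like
## (1.7-3.8e4 per ml) free cyanophage; a true infected fraction averaging
## ~0.79% that doubles at night; and gel assays of 8,000-10,000 cells with
## stage-dependent detection. Every quantity the pipeline later estimates is
## recorded as ground truth, so estimators can be checked by parameter
## recovery.

#' Synthetic campaign configuration
#'
#' Defaults describe the emulated field conditions; see the methods vignette
#' for the rationale behind each value.
#'
#' @param n_days Number of diel cycles (default 7).
#' @param sampling_interval_h Hours between samples (default 4).
#' @param host_mean,host_amplitude Host abundance mean and diel half-range,
#'   cells per ml (defaults 1.75e5 and 0.55e5, spanning 1.2-2.3e5).
#' @param phage_T4_range,phage_T7_range Free-phage concentration ranges,
#'   per ml.
#' @param infection_mean_percent Time-mean true infected fraction, percent
#'   (default 0.79).
#' @param night_day_infection_ratio Night plateau over day plateau of the true
#'   infected fraction (default 2).
#' @param infection_peak_clock `c(start, end)` clock hours of maximal
#'   infection; the night plateau runs from dusk to `end` (default 22-02).
#' @param dusk_h,dawn_h Clock hours of dusk and dawn (defaults 18 and 6).
#' @param latent_period_h Latent period, hours (default 7.9).
#' @param efficiency An [efficiency_model()] shared with the adjustment stage.
#' @param cells_per_gel `c(min, max)` cells loaded per gel (default
#'   8,000-10,000).
#' @param gels_per_sample Replicate gels per sample (default 2).
#' @param cosort_rate Expected false polonies per gel from co-sorted free
#'   viruses (default 0; the filtrate control sees the same rate).
#' @param host_noise_cv,phage_noise_sd,infection_noise_cv Observation/process
#'   noise levels (lognormal CV for host and infection; innovation SD of the
#'   latent AR(1) driving phages).
#' @param stage_phasing Strength of the early-stage shift in infection-stage
#'   occupancy while infection is ramping up (0 = steady-state mix
#'   everywhere).
#' @param start_clock_h Clock hour of the first sample (default 6).
#' @param seed Integer seed; mandatory.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_days = 7, sampling_interval_h = 4,
                       host_mean = 1.75e5, host_amplitude = 0.55e5,
                       phage_T4_range = c(2.7e5, 4.1e5),
                       phage_T7_range = c(1.7e4, 3.8e4),
                       infection_mean_percent = 0.79,
                       night_day_infection_ratio = 2,
                       infection_peak_clock = c(22, 2),
                       dusk_h = 18, dawn_h = 6,
                       latent_period_h = 7.9,
                       efficiency = efficiency_model(),
                       cells_per_gel = c(8000, 10000),
                       gels_per_sample = 2,
                       cosort_rate = 0,
                       host_noise_cv = 0.02,
                       phage_noise_sd = 0.6,
                       infection_noise_cv = 0.05,
                       stage_phasing = 0.3,
                       start_clock_h = 6,
                       seed) {
  if (missing(seed) || is.null(seed)) stopf("`seed` is mandatory in sim_config()")
  check_number(n_days, "n_days", lower = 1)
  check_number(sampling_interval_h, "sampling_interval_h", lower = 0,
               allow_zero_lower = FALSE)
  check_number(infection_mean_percent, "infection_mean_percent", lower = 0)
  check_number(night_day_infection_ratio, "night_day_infection_ratio",
               lower = 0, allow_zero_lower = FALSE)
  for (rng in list(phage_T4_range = phage_T4_range,
                   phage_T7_range = phage_T7_range,
                   cells_per_gel = cells_per_gel)) {
    if (length(rng) != 2 || any(rng <= 0) || rng[1] > rng[2]) {
      stopf("ranges must be positive ordered pairs")
    }
  }
  if (host_amplitude < 0 || host_amplitude >= host_mean) {
    stopf("`host_amplitude` must lie in [0, host_mean)")
  }
  stopifnot(inherits(efficiency, "efficiency_model"))
  structure(list(
    n_days = n_days, sampling_interval_h = sampling_interval_h,
    host_mean = host_mean, host_amplitude = host_amplitude,
    phage_T4_range = phage_T4_range, phage_T7_range = phage_T7_range,
    infection_mean_percent = infection_mean_percent,
    night_day_infection_ratio = night_day_infection_ratio,
    infection_peak_clock = infection_peak_clock,
    dusk_h = dusk_h, dawn_h = dawn_h,
    latent_period_h = latent_period_h, efficiency = efficiency,
    cells_per_gel = cells_per_gel, gels_per_sample = gels_per_sample,
    cosort_rate = cosort_rate, host_noise_cv = host_noise_cv,
    phage_noise_sd = phage_noise_sd, infection_noise_cv = infection_noise_cv,
    stage_phasing = stage_phasing, start_clock_h = start_clock_h,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Diel waveform of the true infected fraction, relative to the day plateau.
# Smoothed square wave: day plateau 1 from dawn to (dusk - ramp); linear rise
# to the night plateau `ratio` reaching it at dusk; plateau until the end of
# the peak window; linear fall back to 1 at dawn.
infection_waveform <- function(clock_h, config) {
  r <- config$night_day_infection_ratio
  dusk <- config$dusk_h
  dawn <- config$dawn_h
  peak_end <- config$infection_peak_clock[2]
  ramp_h <- 4
  h <- clock_h %% 24
  # unwrapped positions relative to dusk
  rel <- (h - dusk) %% 24
  plateau_len <- (peak_end - dusk) %% 24        # dusk -> peak end (8 h default)
  fall_len <- (dawn - peak_end) %% 24           # peak end -> dawn (4 h default)
  day_len <- 24 - plateau_len - fall_len - ramp_h
  ifelse(rel < plateau_len, r,
    ifelse(rel < plateau_len + fall_len,
           r - (r - 1) * (rel - plateau_len) / fall_len,
      ifelse(rel < plateau_len + fall_len + day_len, 1,
             1 + (r - 1) * (rel - plateau_len - fall_len - day_len) / ramp_h)))
}

# Trend indicator of the waveform (-1 falling, 0 plateau, +1 rising), used to
# shift stage occupancy early-stage-heavy while new infections accumulate.
infection_trend <- function(clock_h, config) {
  dusk <- config$dusk_h
  dawn <- config$dawn_h
  peak_end <- config$infection_peak_clock[2]
  ramp_h <- 4
  rel <- (clock_h %% 24 - dusk) %% 24
  plateau_len <- (peak_end - dusk) %% 24
  fall_len <- (dawn - peak_end) %% 24
  day_len <- 24 - plateau_len - fall_len - ramp_h
  ifelse(rel < plateau_len, 0,
    ifelse(rel < plateau_len + fall_len, -1,
      ifelse(rel < plateau_len + fall_len + day_len, 0, 1)))
}

# Host diel waveform in [-1, 1]: night rise from dusk division, small
# pre-dawn loss pulse, daytime decline.
host_waveform <- function(clock_h, config) {
  dusk <- config$dusk_h
  dawn <- config$dawn_h
  rel <- (clock_h %% 24 - dusk) %% 24
  rise_len <- 8                               # dusk -> 02:00 division window
  fall_len <- (dawn - dusk) %% 24 - rise_len  # pre-dawn loss pulse
  day_len <- 24 - rise_len - fall_len
  post_dip <- 0.6
  ifelse(rel < rise_len, -1 + 2 * rel / rise_len,
    ifelse(rel < rise_len + fall_len,
           1 - (1 - post_dip) * (rel - rise_len) / fall_len,
           post_dip - (post_dip + 1) * (rel - rise_len - fall_len) / day_len))
}

# Aperiodic series within a range: latent AR(1), squashed into the range.
aperiodic_series <- function(n, range, ar_sd) {
  z <- numeric(n)
  z[1] <- stats::rnorm(1)
  for (t in seq_len(n)[-1]) {
    z[t] <- 0.6 * z[t - 1] + ar_sd * stats::rnorm(1)
  }
  mid <- mean(range)
  half <- diff(range) / 2
  mid + half * tanh(z)
}

#' Generate a synthetic field campaign
#'
#' @param config A [sim_config()].
#' @return A list with `series` (a [sample_series()] tibble without infection
#'   values: those must be recovered by running the assay pipeline) and
#'   `truth` (tibble of per-timepoint true infected fraction, stage
#'   occupancies, and noiseless channel values). The truth channel never
#'   appears in the emitted series.
#' @export
generate_campaign <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- as.integer(config$n_days * 24 / config$sampling_interval_h)
  time_h <- (seq_len(n) - 1) * config$sampling_interval_h
  clock_h <- (config$start_clock_h + time_h) %% 24
  t0 <- as.POSIXct("2015-07-26 00:00:00", tz = "UTC") +
    config$start_clock_h * 3600
  timestamp <- t0 + time_h * 3600

  with_seed(derive_seed(config$seed, 1), {
    # true infected fraction: normalised waveform times the target mean,
    # with multiplicative lognormal process noise
    w <- infection_waveform(clock_h, config)
    r <- config$night_day_infection_ratio
    mean_w <- (1 + r) / 2  # continuous time-average of the waveform
    base_frac <- config$infection_mean_percent / 100 * w / mean_w
    cv <- config$infection_noise_cv
    noise <- if (cv > 0) {
      stats::rlnorm(n, meanlog = -log(1 + cv^2) / 2, sdlog = sqrt(log(1 + cv^2)))
    } else {
      rep(1, n)
    }
    true_frac <- base_frac * noise

    # stage occupancy: steady state proportional to stage durations, shifted
    # early-stage-heavy while infection is rising and late-heavy while falling
    wts <- config$efficiency$weights
    g <- infection_trend(clock_h, config)
    phi <- config$stage_phasing
    occ <- t(vapply(g, function(gi) {
      u <- wts * exp(phi * gi * c(1, 0, -1))
      u / sum(u)
    }, numeric(3)))

    host_base <- config$host_mean +
      config$host_amplitude * host_waveform(clock_h, config)
    hcv <- config$host_noise_cv
    host <- host_base * if (hcv > 0) {
      stats::rlnorm(n, -log(1 + hcv^2) / 2, sqrt(log(1 + hcv^2)))
    } else {
      rep(1, n)
    }

    phage_T4 <- aperiodic_series(n, config$phage_T4_range, config$phage_noise_sd)
    phage_T7 <- aperiodic_series(n, config$phage_T7_range, config$phage_noise_sd)
    # cell volume shrinks through the night as cells divide and respire
    cell_volume <- 0.15 + 0.05 * cos(2 * pi * (clock_h - config$dusk_h) / 24)

    truth <- tibble::tibble(
      timestamp = timestamp, time_h = time_h, clock_h = clock_h,
      true_fraction = true_frac,
      occ_pre = occ[, 1], occ_during = occ[, 2], occ_post = occ[, 3],
      host_abundance = host, phage_T4 = phage_T4, phage_T7 = phage_T7,
      true_infected_per_ml = true_frac * host
    )

    series <- sample_series(
      timestamp = timestamp, host_abundance = host,
      phage_T4 = phage_T4, phage_T7 = phage_T7,
      vlp = phage_T4 / 0.022,   # T4-like cyanophage are ~2.2% of total VLP
      cell_volume = cell_volume
    )
    list(series = series, truth = truth)
  })
}

#' Simulate replicate gel assays at one timepoint
#'
#' Each gel loads a uniform number of cells from the configured range; the
#' number of truly infected cells is binomial at the true fraction; infected
#' cells are split across infection stages by the true occupancy and detected
#' by binomial thinning at each stage's efficiency; co-sorted free viruses
#' add an independent Poisson count of false polonies, and the filtrate
#' control gel draws only that component.
#'
#' @param true_fraction True infected fraction at the timepoint, in \[0, 1\].
#' @param occupancy Length-3 stage occupancy (sums to 1).
#' @param config A [sim_config()].
#' @param sample_id,phage_family Labels for the emitted gel rows.
#' @param seed Integer seed.
#' @return A gel table (one row per replicate gel) with the true infected
#'   count attached as attribute `"truth"`.
#' @export
simulate_assay <- function(true_fraction, occupancy, config,
                           sample_id = "s1", phage_family = "T4like",
                           seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (true_fraction < 0 || true_fraction > 1) {
    stopf("`true_fraction` must lie in [0, 1]")
  }
  if (abs(sum(occupancy) - 1) > 1e-6) stopf("`occupancy` must sum to 1")
  e <- config$efficiency$efficiencies
  with_seed(seed, {
    gels <- lapply(seq_len(config$gels_per_sample), function(gidx) {
      rng <- config$cells_per_gel
      cells <- if (rng[1] == rng[2]) rng[1] else sample(seq(rng[1], rng[2]), 1)
      infected <- stats::rbinom(1, cells, true_fraction)
      stages <- if (infected > 0) {
        drop(stats::rmultinom(1, infected, occupancy))
      } else {
        c(0L, 0L, 0L)
      }
      detected <- sum(stats::rbinom(3, stages, e))
      cosort <- if (config$cosort_rate > 0) {
        stats::rpois(1, config$cosort_rate)
      } else {
        0L
      }
      filtrate <- if (config$cosort_rate > 0) {
        stats::rpois(1, config$cosort_rate)
      } else {
        0L
      }
      gel <- gel_assay(polony_count = detected + cosort, cells_loaded = cells,
                      filtrate_polony_count = filtrate,
                      phage_family = phage_family,
                      replicate_id = paste0("r", gidx), sample_id = sample_id)
      gel$true_infected <- infected
      gel
    })
    out <- dplyr::bind_rows(gels)
    truth <- sum(out$true_infected)
    out$true_infected <- NULL
    attr(out, "truth") <- truth
    validate_gel_table(out)
  })
}

#' Simulate gel assays for every timepoint of a campaign
#'
#' @param campaign Output of [generate_campaign()].
#' @param config The same [sim_config()].
#' @return A gel table with a `sample_id` of the form `t001, t002, ...`
#'   matching campaign row order, plus a `timestamp` column.
#' @export
simulate_campaign_assays <- function(campaign, config) {
  truth <- campaign$truth
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    g <- simulate_assay(
      true_fraction = truth$true_fraction[i],
      occupancy = c(truth$occ_pre[i], truth$occ_during[i], truth$occ_post[i]),
      config = config,
      sample_id = sprintf("t%03d", i),
      seed = derive_seed(config$seed, 100 + i)
    )
    g$timestamp <- truth$timestamp[i]
    g
  })
  validate_gel_table(dplyr::bind_rows(rows))
}

#' End-to-end parameter recovery on a synthetic campaign
#'
#' Runs the full chain - campaign generation, assay simulation, co-sorting
#' correction, replicate pooling, bootstrap efficiency adjustment, and diel
#' analysis - then compares recovered quantities with the generator's ground
#' truth.
#'
#' @param config A [sim_config()].
#' @param bootstrap A [bootstrap_config()] (its seed is re-derived per
#'   timepoint from the campaign seed).
#' @param qc A [gel_qc_policy()].
#' @param windows A [diel_windows()].
#' @return A list: `mean_true_percent`, `mean_recovered_percent`,
#'   `relative_bias` (signed, fraction), `night_day_ratio` (recovered, on
#'   adjusted percent), `night_day_ratio_true`, `ci_coverage` (fraction of
#'   timepoints whose CI covers the true percent), `n_censored`, `series`
#'   (sample series with recovered infection), `per_sample` (tibble of
#'   per-timepoint estimates, CIs and truth).
#' @export
end_to_end_recovery <- function(config,
                                bootstrap = bootstrap_config(iterations = 1000),
                                qc = gel_qc_policy(),
                                windows = diel_windows()) {
  campaign <- generate_campaign(config)
  gels <- simulate_campaign_assays(campaign, config)
  truth <- campaign$truth

  ids <- sprintf("t%03d", seq_len(nrow(truth)))
  est <- lapply(seq_along(ids), function(i) {
    sub <- gels[gels$sample_id == ids[i], ]
    corrected <- correct_cosort_empirical(sub$polony_count,
                                          sub$filtrate_polony_count)
    pooled <- pool_replicates(sub, qc = qc, counts = corrected)
    bc <- bootstrap_config(iterations = bootstrap$iterations,
                           level = bootstrap$level,
                           seed = derive_seed(config$seed, 5000 + i),
                           count_resampling = bootstrap$count_resampling)
    adj <- bootstrap_adjust(pooled$polonies, pooled$cells,
                            model = config$efficiency, config = bc,
                            lod_polonies = qc$min_polonies)
    tibble::tibble(
      sample_id = ids[i],
      percent_raw = pooled$percent,
      percent_adjusted = adj$point,
      ci_low = adj$ci[["lower"]], ci_high = adj$ci[["upper"]],
      censored = pooled$censored,
      true_percent = 100 * truth$true_fraction[i]
    )
  })
  est <- dplyr::bind_rows(est)

  series <- campaign$series
  series$infected_percent <- est$percent_adjusted
  series$infected_per_ml <-
    infected_cells_per_ml(est$percent_adjusted, series$host_abundance)

  covered <- est$ci_low <= est$true_percent & est$true_percent <= est$ci_high
  mean_true <- mean(est$true_percent)
  mean_rec <- mean(est$percent_adjusted)
  dn <- day_night_ratio(series$infected_percent, series$clock_h, windows)
  dn_true <- day_night_ratio(est$true_percent, series$clock_h, windows)

  list(
    mean_true_percent = mean_true,
    mean_recovered_percent = mean_rec,
    relative_bias = mean_rec / mean_true - 1,
    night_day_ratio = dn$ratio,
    night_day_ratio_true = dn_true$ratio,
    ci_coverage = mean(covered),
    n_censored = sum(est$censored),
    series = series,
    per_sample = est
  )
}
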