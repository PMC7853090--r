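## Diel (24-h) periodicity analysis of infection and abundance series.
##
## Field campaigns sample every 4 h over several diel cycles. Percent
## infection of Prochlorococcus oscillates with the light-dark cycle (roughly
## 2-fold higher at night) while free-phage standing stocks do not. The tests
## here detect that periodicity, quantify the day-night contrast, and close
## the nightly production budget implied by synchronous dusk division.

#' Assemble and validate a field sample series
#'
#' @param timestamp `POSIXct` sampling instants in local solar time, strictly
#'   increasing, nominally 4-hourly (gaps allowed).
#' @param host_abundance Host cells per ml.
#' @param phage_T4,phage_T7 Free cyanophage concentrations per ml.
#' @param vlp Optional virus-like-particle counts per ml.
#' @param cell_volume Optional mean cell volume, um^3.
#' @param infected_percent Optional percent infection (adjusted).
#' @param infected_per_ml Optional infected-cell concentration per ml; filled
#'   from `infected_percent` and `host_abundance` when absent.
#' @return A tibble with class `"sample_series"` and a `time_h` column (hours
#'   since the first sample) plus `clock_h` (local clock hour).
#' @export
sample_series <- function(timestamp, host_abundance, phage_T4, phage_T7,
                          vlp = NA_real_, cell_volume = NA_real_,
                          infected_percent = NA_real_,
                          infected_per_ml = NA_real_) {
  if (!inherits(timestamp, "POSIXct")) {
    stopf("`timestamp` must be POSIXct")
  }
  if (is.unsorted(as.numeric(timestamp), strictly = TRUE)) {
    stopf("timestamps must be strictly increasing")
  }
  tbl <- tibble::tibble(
    timestamp = timestamp,
    host_abundance = as.double(host_abundance),
    phage_T4 = as.double(phage_T4),
    phage_T7 = as.double(phage_T7),
    vlp = as.double(vlp),
    cell_volume = as.double(cell_volume),
    infected_percent = as.double(infected_percent),
    infected_per_ml = as.double(infected_per_ml)
  )
  conc <- c("host_abundance", "phage_T4", "phage_T7", "vlp", "infected_per_ml")
  for (col in conc) {
    v <- tbl[[col]]
    if (any(!is.na(v) & v < 0)) stopf("`%s` must be non-negative", col)
  }
  fill <- is.na(tbl$infected_per_ml) & !is.na(tbl$infected_percent)
  tbl$infected_per_ml[fill] <-
    infected_cells_per_ml(tbl$infected_percent[fill], tbl$host_abundance[fill])
  tbl$time_h <- as.numeric(difftime(tbl$timestamp, tbl$timestamp[1],
                                    units = "hours"))
  lt <- as.POSIXlt(tbl$timestamp)
  tbl$clock_h <- lt$hour + lt$min / 60 + lt$sec / 3600
  class(tbl) <- unique(c("sample_series", class(tbl)))
  tbl
}

#' Day and night clock windows
#'
#' Clock intervals are half-open `[start, end)` in local solar time and may
#' wrap midnight (the default night window 18:00-02:00 does).
#'
#' @param night,day Numeric `c(start_hour, end_hour)` clock intervals
#'   (defaults 18-02 and 06-14).
#' @param period Period length in hours (default 24).
#' @return A `diel_windows` list.
#' @export
diel_windows <- function(night = c(18, 2), day = c(6, 14), period = 24) {
  check_number(period, "period", lower = 0, allow_zero_lower = FALSE)
  for (w in list(night = night, day = day)) {
    if (length(w) != 2 || any(w < 0) || any(w >= period)) {
      stopf("window bounds must be clock hours in [0, period)")
    }
  }
  wins <- structure(list(night = night, day = day, period = period),
                    class = "diel_windows")
  grid <- seq(0, period, by = 1 / 60)
  if (any(in_clock_window(grid, night, period) &
          in_clock_window(grid, day, period))) {
    stopf("night and day windows must not overlap")
  }
  wins
}

# half-open [start, end) membership, wrapping the period boundary
in_clock_window <- function(clock_h, window, period = 24) {
  h <- clock_h %% period
  if (window[1] <= window[2]) {
    h >= window[1] & h < window[2]
  } else {
    h >= window[1] | h < window[2]
  }
}

#' Permutation harmonic test for diel rhythmicity
#'
#' Fits a single sinusoid of the given period to the series by least squares
#' and uses its amplitude as the test statistic. The null distribution is
#' obtained by permuting the observed values across the fixed sampling times,
#' which destroys any time structure while conditioning on the observed value
#' set; the p-value is the permutation tail probability (with the add-one
#' correction, so p is in (0, 1\]). This is a self-contained, assumption-light
#' stand-in for rank-based rhythmicity tests; it is calibrated by
#' construction and makes no claim to reproduce their p-values.
#'
#' @param values Numeric series (no `NA`s used; missing values dropped with
#'   their times).
#' @param time_h Sampling times in hours, same length as `values`.
#' @param period Period to test, hours (default 24).
#' @param n_permutations Number of permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @return A list: `p_value`, `amplitude` (fitted harmonic amplitude),
#'   `mesor` (fitted mean), `peak_h` (clock hour of the fitted peak),
#'   `n_permutations`, `seed`.
#' @export
rhythmicity_test <- function(values, time_h, period = 24,
                             n_permutations = 999, seed = 1L) {
  keep <- !is.na(values)
  values <- values[keep]
  time_h <- time_h[keep]
  n <- length(values)
  if (n != length(time_h)) stopf("`values` and `time_h` lengths differ")
  span <- diff(range(time_h))
  if (span < 2 * period) {
    stopf("insufficient coverage: need >= 2 full periods, have %.1f h", span)
  }
  if (n < 4 * span / period) {
    stopf("insufficient coverage: need >= 4 samples per period")
  }

  omega <- 2 * pi / period
  X <- cbind(1, cos(omega * time_h), sin(omega * time_h))
  # hat matrix pieces reused for every permutation: coefficients are linear
  # in the response, so permutations reduce to one matrix product
  M <- solve(crossprod(X), t(X))
  obs_coef <- drop(M %*% values)
  obs_amp <- sqrt(obs_coef[2]^2 + obs_coef[3]^2)

  perm_amp <- with_seed(seed, {
    P <- matrix(0, nrow = length(values), ncol = n_permutations)
    for (j in seq_len(n_permutations)) P[, j] <- sample(values)
    cf <- M %*% P
    sqrt(cf[2, ]^2 + cf[3, ]^2)
  })

  p <- (1 + sum(perm_amp >= obs_amp)) / (1 + n_permutations)
  peak <- (atan2(obs_coef[3], obs_coef[2]) / omega) %% period
  list(p_value = p, amplitude = obs_amp, mesor = obs_coef[1],
       peak_h = peak, n_permutations = n_permutations, seed = seed)
}

#' Night-to-day fold ratio of a series
#'
#' Mean over samples falling in the night clock window divided by the mean
#' over samples in the day window. Invariant to rescaling the whole series.
#'
#' @param values Numeric series.
#' @param clock_h Local clock hour of each sample.
#' @param windows A [diel_windows()].
#' @return A list: `ratio`, `night_mean`, `day_mean`, `n_night`, `n_day`.
#' @export
day_night_ratio <- function(values, clock_h, windows = diel_windows()) {
  keep <- !is.na(values)
  values <- values[keep]
  clock_h <- clock_h[keep]
  night <- in_clock_window(clock_h, windows$night, windows$period)
  day <- in_clock_window(clock_h, windows$day, windows$period)
  if (!any(night)) stopf("empty window: no samples in the night window")
  if (!any(day)) stopf("empty window: no samples in the day window")
  nm <- mean(values[night])
  dm <- mean(values[day])
  list(ratio = nm / dm, night_mean = nm, day_mean = dm,
       n_night = sum(night), n_day = sum(day))
}

#' Nightly production budget of the host population
#'
#' Synchronously dividing hosts should add `division_fraction x pre-dusk
#' abundance` cells each night if nothing died. The shortfall between that
#' expectation and the observed post-dusk increase is the implied nightly
#' loss. The identity `expected = observed + loss` holds exactly.
#'
#' @param host Host abundance series, cells per ml.
#' @param time_h Hours since the series start.
#' @param clock_h Local clock hour per sample.
#' @param dusk_h,dawn_h Clock hours bounding the night (defaults 18 and 6).
#' @param division_fraction Fraction of the population dividing per day
#'   (default 1: one doubling).
#' @return A tibble with one row per night: `night`, `pre_dusk`, `expected`,
#'   `observed`, `implied_loss`.
#' @export
nightly_budget <- function(host, time_h, clock_h, dusk_h = 18, dawn_h = 6,
                           division_fraction = 1) {
  check_number(division_fraction, "division_fraction", lower = 0)
  # anchor each night at the last sample at/before dusk of that solar day
  abs_clock <- clock_h[1] + time_h - time_h[1]  # continuous clock, unwrapped
  night_id <- floor((abs_clock - dusk_h) / 24)
  nights <- sort(unique(night_id[night_id >= 0 & abs_clock >= dusk_h]))
  rows <- lapply(nights, function(k) {
    dusk_t <- dusk_h + 24 * k
    dawn_t <- dusk_t + ((dawn_h - dusk_h) %% 24)
    pre <- which(abs_clock <= dusk_t)
    post <- which(abs_clock > dusk_t & abs_clock <= dawn_t)
    if (length(pre) == 0) stopf("missing dusk anchor sample for night %d", k + 1)
    if (length(post) == 0) return(NULL)
    pre_dusk <- host[max(pre)]
    expected <- division_fraction * pre_dusk
    observed <- max(host[post]) - pre_dusk
    tibble::tibble(night = k + 1, pre_dusk = pre_dusk, expected = expected,
                   observed = observed, implied_loss = expected - observed)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) stopf("missing dusk anchor sample: series spans no night")
  out
}

#' Infected-cell concentration from percent infection
#'
#' @param percent Percent infection.
#' @param host_abundance Host cells per ml.
#' @return Infected cells per ml.
#' @export
#' @examples
#' infected_cells_per_ml(0.35, 1.49e5)  # ~521 cells per ml
infected_cells_per_ml <- function(percent, host_abundance) {
  if (any(percent < 0, na.rm = TRUE) || any(host_abundance < 0, na.rm = TRUE)) {
    stopf("inputs must be non-negative")
  }
  percent / 100 * host_abundance
}
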