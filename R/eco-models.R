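## Encounter-rate, mortality, and phage-turnover arithmetic.
##
## Encounter-rate theory for a diffusing virus and a spherical host gives the
## encounter kernel beta = 2*pi*d*D (cm^3 s^-1) for host diameter d and virus
## diffusivity D, ignoring infectivity and susceptibility. Combined with
## ambient concentrations, beta yields per-cell encounter intervals,
## population encounter totals, and a theoretical mortality ceiling against
## which measured instantaneous infection is compared. Instantaneous
## infection converts to daily mortality through the number of lytic cycles
## completed per day (latent period ~7.9 h for T4-like cyanophages, clamped
## to 1-3 cycles).

#' Diffusive encounter kernel
#'
#' @param host_diameter Host cell diameter, um.
#' @param virus_diffusivity Virus diffusion coefficient, cm^2 s^-1.
#' @return Encounter kernel beta, cm^3 s^-1.
#' @export
#' @examples
#' encounter_kernel(1, 1e-7)  # 6.283e-11
encounter_kernel <- function(host_diameter, virus_diffusivity) {
  check_number(host_diameter, "host_diameter", lower = 0, allow_zero_lower = FALSE)
  check_number(virus_diffusivity, "virus_diffusivity", lower = 0,
               allow_zero_lower = FALSE)
  2 * pi * (host_diameter * 1e-4) * virus_diffusivity
}

#' Calibrate the encounter kernel from an observed encounter interval
#'
#' Inverse of [per_cell_encounter_rate()]: given that one cell encounters one
#' phage every `interval_h` hours at concentration `phage_conc`, the implied
#' kernel is `1 / (interval_s * conc)`.
#'
#' @param interval_h Per-cell encounter interval, hours.
#' @param phage_conc Free-phage concentration, per ml.
#' @return Kernel beta, cm^3 s^-1.
#' @export
#' @examples
#' calibrate_beta(54, 3.3e5)  # 1.56e-11
calibrate_beta <- function(interval_h, phage_conc) {
  check_number(interval_h, "interval_h", lower = 0, allow_zero_lower = FALSE)
  check_number(phage_conc, "phage_conc", lower = 0, allow_zero_lower = FALSE)
  1 / (interval_h * 3600 * phage_conc)
}

#' Encounter model (kernel or calibrated)
#'
#' The default mode calibrates beta against a per-cell encounter interval of
#' 54 h at 3.3e5 phages per ml; kernel mode computes beta = 2*pi*d*D from
#' physical parameters for sensitivity analysis.
#'
#' @param mode `"calibrated"` or `"kernel"`.
#' @param per_cell_interval_h,phage_conc Calibration pair (calibrated mode).
#' @param host_diameter,virus_diffusivity Physical parameters (kernel mode).
#' @return An `encounter_model` list with element `beta` (cm^3 s^-1).
#' @export
encounter_model <- function(mode = c("calibrated", "kernel"),
                            per_cell_interval_h = 54, phage_conc = 3.3e5,
                            host_diameter = NULL, virus_diffusivity = NULL) {
  mode <- match.arg(mode)
  beta <- switch(mode,
    calibrated = calibrate_beta(per_cell_interval_h, phage_conc),
    kernel = encounter_kernel(host_diameter, virus_diffusivity)
  )
  structure(list(mode = mode, beta = beta,
                 calibration = if (mode == "calibrated") {
                   list(per_cell_interval_h = per_cell_interval_h,
                        phage_conc = phage_conc)
                 }),
            class = "encounter_model")
}

#' Per-cell encounter rate and interval
#'
#' @param beta Encounter kernel, cm^3 s^-1 (1 ml = 1 cm^3).
#' @param phage_conc Free-phage concentration, per ml.
#' @return A list: `rate_per_day` (encounters per cell per day) and
#'   `interval_h` (hours between encounters; `Inf` at zero concentration).
#' @export
per_cell_encounter_rate <- function(beta, phage_conc) {
  check_number(beta, "beta", lower = 0)
  check_number(phage_conc, "phage_conc", lower = 0)
  rate <- beta * phage_conc * 86400
  list(rate_per_day = rate, interval_h = if (rate > 0) 24 / rate else Inf)
}

#' Population-level daily encounter total
#'
#' @param per_cell_rate Encounters per cell per day.
#' @param host_conc Host cells per ml.
#' @return Encounters per ml per day (full precision; see
#'   [report_encounters()] for 1-significant-figure reporting).
#' @export
population_daily_encounters <- function(per_cell_rate, host_conc) {
  check_number(per_cell_rate, "per_cell_rate", lower = 0)
  check_number(host_conc, "host_conc", lower = 0)
  per_cell_rate * host_conc
}

#' Theoretical maximum daily mortality from encounters
#'
#' If every encounter led to infection and lysis, the fraction of the host
#' population killed daily would be the encounter total over the standing
#' stock, capped at 100%.
#'
#' @param encounters Encounters per ml per day.
#' @param host_conc Host cells per ml, > 0.
#' @return Percent of hosts killed per day.
#' @export
max_daily_mortality <- function(encounters, host_conc) {
  check_number(encounters, "encounters", lower = 0)
  check_number(host_conc, "host_conc", lower = 0, allow_zero_lower = FALSE)
  min(100 * encounters / host_conc, 100)
}

#' Lytic cycles completed per day
#'
#' @param latent_period_h Latent period, hours.
#' @param clamp Integer `c(low, high)` range for the usable cycle count
#'   (default 1-3).
#' @return A list: `raw` (24 / latent period) and `clamped` (whole cycles,
#'   restricted to the clamp range).
#' @export
#' @examples
#' cycles_per_day(7.9)  # raw 3.04, clamped 3
cycles_per_day <- function(latent_period_h, clamp = c(1L, 3L)) {
  check_number(latent_period_h, "latent_period_h", lower = 0,
               allow_zero_lower = FALSE)
  if (length(clamp) != 2 || clamp[1] < 1 || clamp[1] > clamp[2]) {
    stopf("`clamp` must be an ordered pair with low >= 1")
  }
  raw <- 24 / latent_period_h
  list(raw = raw, clamped = as.integer(min(max(floor(raw), clamp[1]), clamp[2])))
}

#' Mortality model: instantaneous infection to daily mortality
#'
#' @param latent_period_h Latent period, hours (default 7.9, the mean for
#'   cultured T4-like cyanophages).
#' @param cycles_range Integer `c(low, high)` infection cycles per day
#'   (default 1-3).
#' @param instantaneous_range Percent `c(low, high)` instantaneous infection.
#' @return A `mortality_model` list.
#' @export
mortality_model <- function(latent_period_h = 7.9, cycles_range = c(1L, 3L),
                            instantaneous_range = c(0.35, 1.6)) {
  check_number(latent_period_h, "latent_period_h", lower = 0,
               allow_zero_lower = FALSE)
  if (length(cycles_range) != 2 || cycles_range[1] < 1 ||
      cycles_range[1] > cycles_range[2]) {
    stopf("`cycles_range` must be an ordered integer pair with low >= 1")
  }
  if (length(instantaneous_range) != 2 || any(instantaneous_range < 0) ||
      instantaneous_range[1] > instantaneous_range[2]) {
    stopf("`instantaneous_range` must be an ordered non-negative pair")
  }
  structure(list(latent_period_h = latent_period_h,
                 cycles_range = as.integer(cycles_range),
                 instantaneous_range = instantaneous_range),
            class = "mortality_model")
}

#' Bounds on daily host mortality
#'
#' Mortality is lysis, so daily mortality is instantaneous infection times
#' the number of lytic cycles completed per day: the lower bound pairs the
#' low instantaneous value with the low cycle count, the upper bound the high
#' value with the high count.
#'
#' @param model A [mortality_model()].
#' @return Named numeric `c(low, high)`, percent per day.
#' @export
#' @examples
#' daily_mortality_bounds(mortality_model())  # 0.35 and 4.8 percent per day
daily_mortality_bounds <- function(model = mortality_model()) {
  stopifnot(inherits(model, "mortality_model"))
  c(low = model$instantaneous_range[1] * model$cycles_range[1],
    high = model$instantaneous_range[2] * model$cycles_range[2])
}

#' Fraction of encounters that result in infection
#'
#' @param daily_infected Newly infected cells per ml per day.
#' @param encounters Encounters per ml per day, > 0.
#' @return Percent of encounters producing an infection.
#' @export
fraction_encounters_infective <- function(daily_infected, encounters) {
  check_number(daily_infected, "daily_infected", lower = 0)
  if (encounters <= 0) stopf("`encounters` must be positive")
  100 * daily_infected / encounters
}

#' Phage standing-stock turnover model
#'
#' @param standing_stock Free-phage concentration, per ml (default 3.3e5,
#'   T4-like cyanophages).
#' @param burst_size Progeny virions per lysed cell (default 12).
#' @param lysed_per_cycle Host cells lysed per ml per infection cycle
#'   (default 1200).
#' @param cycles_per_day Infection cycles per day.
#' @return A `turnover_model` list.
#' @export
turnover_model <- function(standing_stock = 3.3e5, burst_size = 12,
                           lysed_per_cycle = 1200, cycles_per_day = 1L) {
  for (nm in c("standing_stock", "burst_size", "lysed_per_cycle",
               "cycles_per_day")) {
    check_number(get(nm), nm, lower = 0, allow_zero_lower = FALSE)
  }
  structure(list(standing_stock = standing_stock, burst_size = burst_size,
                 lysed_per_cycle = lysed_per_cycle,
                 cycles_per_day = cycles_per_day),
            class = "turnover_model")
}

#' Turnover time of the free-phage standing stock
#'
#' Days needed for lysis-driven production (burst size x cells lysed per
#' cycle x cycles per day) to replace the standing stock.
#'
#' @param model A [turnover_model()].
#' @return Turnover time in days.
#' @export
#' @examples
#' phage_turnover_time(turnover_model(cycles_per_day = 1))  # 22.9 d
#' phage_turnover_time(turnover_model(cycles_per_day = 3))  # 7.6 d
phage_turnover_time <- function(model = turnover_model()) {
  stopifnot(inherits(model, "turnover_model"))
  model$standing_stock /
    (model$burst_size * model$lysed_per_cycle * model$cycles_per_day)
}

#' Burst size required to explain an observed phage increase
#'
#' @param phage_increase Increase in free phages, per ml.
#' @param infected_increase Increase in infected cells, per ml, > 0.
#' @return Required burst size, phages per cell.
#' @export
#' @examples
#' required_burst_size(76000, 500)  # 152, ~150 after report rounding
required_burst_size <- function(phage_increase, infected_increase) {
  check_number(phage_increase, "phage_increase", lower = 0)
  if (infected_increase <= 0) stopf("`infected_increase` must be positive")
  phage_increase / infected_increase
}

#' Reconcile observed infection with encounter theory
#'
#' Encounters vastly outnumber realised infections. If a single mechanism
#' absorbed the whole gap, the required fraction is the same for each
#' candidate: the fraction of phages that are infectious, the fraction of
#' encounters ending in adsorption, or the fraction of hosts that are
#' susceptible (whose complement is the resistant fraction). If instead three
#' multiplicative mechanisms share the gap equally, each is the cube root of
#' the infection-to-encounter ratio.
#'
#' @param daily_infected Newly infected cells per ml per day.
#' @param encounters Encounters per ml per day, > 0.
#' @param host_conc Host cells per ml, > 0 (used to express the resistant
#'   fraction as an absolute concentration).
#' @return A list: `f_infectious`, `f_adsorb`, `f_susceptible`, `f_resistant`,
#'   `combined_balanced` (all percents) and `resistant_per_ml`.
#' @export
#' @examples
#' reconcile_mechanisms(3010, 70000, 1.6e5)
reconcile_mechanisms <- function(daily_infected, encounters, host_conc) {
  check_number(daily_infected, "daily_infected", lower = 0)
  if (encounters <= 0) stopf("`encounters` must be positive")
  if (host_conc <= 0) stopf("`host_conc` must be positive")
  ratio <- daily_infected / encounters
  if (ratio > 1) {
    warning("daily_infected exceeds encounters: mechanism fractions > 100%",
            call. = FALSE)
  }
  f <- 100 * ratio
  list(
    f_infectious = f,
    f_adsorb = f,
    f_susceptible = f,
    f_resistant = 100 - f,
    combined_balanced = 100 * ratio^(1 / 3),
    resistant_per_ml = (1 - ratio) * host_conc
  )
}
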