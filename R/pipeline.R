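## Formats, configuration and orchestration.
##
## One configuration object drives the whole chain: simulate (or read) gel
## counts, quantify percent infection with co-sorting corrections and QC,
## adjust for stage-dependent detection efficiency with bootstrap
## uncertainty, analyse diel structure, and convert to ecological rates.
## All tables are comma-separated UTF-8 with a header row, '.' decimal and
## ISO-8601 timestamps; the JSON summary carries the headline numbers.

GEL_TABLE_COLUMNS <- c("sample_id", "timestamp_iso8601", "phage_family",
                       "cells_loaded", "polony_count",
                       "filtrate_polony_count", "replicate_id")

#' Read a gel table from CSV
#'
#' Expects columns `sample_id, timestamp_iso8601, phage_family, cells_loaded,
#' polony_count, filtrate_polony_count, replicate_id` (filtrate may be
#' empty). Malformed rows (non-positive cells, negative counts, unknown
#' family) are dropped and collected, with their line numbers, in the
#' `"errors"` attribute of the result; a missing required column is an error.
#'
#' @param path Path to the CSV file.
#' @return A validated gel table with a `timestamp` column; attribute
#'   `"errors"` holds a tibble of rejected rows (`line`, `reason`).
#' @export
read_gel_table <- function(path) {
  if (!file.exists(path)) stopf("gel table not found: %s", path)
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(GEL_TABLE_COLUMNS, names(raw))
  if (length(missing) > 0) {
    stopf("gel table %s is missing required column(s): %s",
          path, paste(missing, collapse = ", "))
  }
  n <- nrow(raw)
  cells <- suppressWarnings(as.double(raw$cells_loaded))
  polonies <- suppressWarnings(as.double(raw$polony_count))
  filtrate <- suppressWarnings(as.double(raw$filtrate_polony_count))
  reason <- rep(NA_character_, n)
  reason[is.na(cells) | cells <= 0] <- "cells_loaded must be a positive number"
  reason[is.na(polonies) | polonies < 0] <-
    "polony_count must be a non-negative number"
  reason[!raw$phage_family %in% PHAGE_FAMILIES] <- "unknown phage_family"
  bad <- !is.na(reason)

  tbl <- tibble::tibble(
    sample_id = raw$sample_id[!bad],
    phage_family = raw$phage_family[!bad],
    replicate_id = raw$replicate_id[!bad],
    cells_loaded = cells[!bad],
    polony_count = polonies[!bad],
    filtrate_polony_count = filtrate[!bad],
    timestamp = as.POSIXct(raw$timestamp_iso8601[!bad],
                           format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  )
  out <- validate_gel_table(tbl)
  attr(out, "errors") <- tibble::tibble(
    line = which(bad) + 1L,  # +1 for the header row
    reason = reason[bad]
  )
  out
}

#' Write a gel table to CSV
#'
#' Emits the reading schema plus derived columns `percent_raw`,
#' `percent_cosort_corrected` (filtrate-subtracted where a control exists,
#' unchanged otherwise) and `qc_status`.
#'
#' @param gels A gel table with a `timestamp` column.
#' @param path Output CSV path.
#' @param qc A [gel_qc_policy()].
#' @return The written tibble, invisibly.
#' @export
write_gel_table <- function(gels, path, qc = gel_qc_policy()) {
  gels <- validate_gel_table(tibble::as_tibble(gels))
  has_control <- !is.na(gels$filtrate_polony_count)
  corrected <- gels$polony_count
  corrected[has_control] <- correct_cosort_empirical(
    gels$polony_count[has_control], gels$filtrate_polony_count[has_control])
  out <- tibble::tibble(
    sample_id = gels$sample_id,
    timestamp_iso8601 = format(gels$timestamp, "%Y-%m-%dT%H:%M:%S%z"),
    phage_family = gels$phage_family,
    cells_loaded = gels$cells_loaded,
    polony_count = gels$polony_count,
    filtrate_polony_count = gels$filtrate_polony_count,
    replicate_id = gels$replicate_id,
    percent_raw = raw_percent_infection(gels$polony_count, gels$cells_loaded),
    percent_cosort_corrected = raw_percent_infection(corrected,
                                                     gels$cells_loaded),
    qc_status = qc_gel(corrected, qc)
  )
  readr::write_csv(out, path)
  invisible(out)
}

#' Pipeline configuration
#'
#' Bundles every stage's configuration; all components validate at
#' construction, before any stage runs. Unknown arguments are rejected.
#'
#' @param sim A [sim_config()] (used when no input gel table is given).
#' @param input_gel_table Optional path to a gel-table CSV to analyse instead
#'   of simulating.
#' @param out_dir Optional output directory; when `NULL` nothing is written.
#' @param cosort A [cosort_policy()].
#' @param qc A [gel_qc_policy()].
#' @param efficiency An [efficiency_model()].
#' @param bootstrap A [bootstrap_config()].
#' @param windows A [diel_windows()].
#' @param encounter An [encounter_model()].
#' @param mortality Optional [mortality_model()]; when `NULL` the
#'   instantaneous-infection range is taken from the data.
#' @param turnover A [turnover_model()].
#' @param n_permutations Permutations for the rhythmicity test.
#' @param seed Global seed; stage seeds derive from it.
#' @param log_level `"info"` or `"quiet"`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = NULL, input_gel_table = NULL, out_dir = NULL,
                            cosort = cosort_policy(), qc = gel_qc_policy(),
                            efficiency = efficiency_model(),
                            bootstrap = bootstrap_config(iterations = 2000),
                            windows = diel_windows(),
                            encounter = encounter_model(),
                            mortality = NULL,
                            turnover = turnover_model(),
                            n_permutations = 999,
                            seed = 1L, log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  if (is.null(sim) && is.null(input_gel_table)) {
    sim <- sim_config(seed = seed)
  }
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  stopifnot(inherits(cosort, "cosort_policy"), inherits(qc, "gel_qc_policy"),
            inherits(efficiency, "efficiency_model"),
            inherits(bootstrap, "bootstrap_config"),
            inherits(windows, "diel_windows"),
            inherits(encounter, "encounter_model"),
            inherits(turnover, "turnover_model"))
  if (!is.null(mortality)) stopifnot(inherits(mortality, "mortality_model"))
  check_number(n_permutations, "n_permutations", lower = 1)
  structure(list(sim = sim, input_gel_table = input_gel_table,
                 out_dir = out_dir, cosort = cosort, qc = qc,
                 efficiency = efficiency, bootstrap = bootstrap,
                 windows = windows, encounter = encounter,
                 mortality = mortality, turnover = turnover,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), log_level = log_level),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised top-level keys mirror the [pipeline_config()] arguments, each
#' holding that component's fields (e.g. `qc: {min_polonies: 5}`). Unknown
#' keys are rejected before anything runs.
#'
#' @param path YAML file path.
#' @param seed Optional seed overriding the file's `seed` key (a command-line
#'   `--seed` takes precedence over the config file).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  known <- c("sim", "input_gel_table", "out_dir", "cosort", "qc",
             "efficiency", "bootstrap", "windows", "encounter", "turnover",
             "mortality", "n_permutations", "seed", "log_level")
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0) {
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  }
  if (!is.null(seed)) y$seed <- seed
  if (is.null(y$seed)) y$seed <- 1L
  build <- function(key, ctor, ...) {
    if (is.null(y[[key]])) return(NULL)
    do.call(ctor, c(y[[key]], ...))
  }
  eff <- build("efficiency", efficiency_model)
  args <- list(
    input_gel_table = y$input_gel_table, out_dir = y$out_dir,
    seed = y$seed
  )
  if (!is.null(y$sim)) {
    sim_args <- y$sim
    if (is.null(sim_args$seed)) sim_args$seed <- y$seed
    if (!is.null(eff)) sim_args$efficiency <- eff
    args$sim <- do.call(sim_config, sim_args)
  }
  if (!is.null(eff)) args$efficiency <- eff
  for (key in c("cosort", "qc", "bootstrap", "windows", "encounter",
                "turnover", "mortality")) {
    ctor <- switch(key, cosort = cosort_policy, qc = gel_qc_policy,
                   bootstrap = bootstrap_config, windows = diel_windows,
                   encounter = encounter_model, turnover = turnover_model,
                   mortality = mortality_model)
    comp <- build(key, ctor)
    if (!is.null(comp)) args[[key]] <- comp
  }
  if (!is.null(y$n_permutations)) args$n_permutations <- y$n_permutations
  if (!is.null(y$log_level)) args$log_level <- y$log_level
  do.call(pipeline_config, args)
}

pipeline_log <- function(config, messages, ...) {
  msg <- sprintf(...)
  if (config$log_level == "info") message(msg)
  c(messages, paste(format(Sys.time(), "%H:%M:%S"), msg))
}

#' Run the full analysis pipeline
#'
#' Executes quantify -> adjust -> diel -> ecology in order, starting from
#' either a simulated campaign (the default) or a gel-table CSV. When
#' `out_dir` is set, writes per-stage CSVs (`gels.csv`, `quantify.csv`,
#' `diel.csv`, `ecology.csv`, and `ground_truth.csv` for simulated input), a
#' `summary.json` of headline numbers, and `pipeline.log`. Rerunning with the
#' same configuration reproduces every output.
#'
#' @param config A [pipeline_config()].
#' @return A report bundle (list): `samples` (per-sample estimates),
#'   `series`, `diel`, `ecology`, `summary`, `log`. Invisible.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  logs <- character()

  ## ---- input: simulate or read -------------------------------------------
  truth <- NULL
  if (is.null(config$input_gel_table)) {
    logs <- pipeline_log(config, logs, "simulate: seed %d", config$sim$seed)
    campaign <- generate_campaign(config$sim)
    gels <- simulate_campaign_assays(campaign, config$sim)
    series <- campaign$series
    truth <- campaign$truth
  } else {
    logs <- pipeline_log(config, logs, "read: %s", config$input_gel_table)
    gels <- read_gel_table(config$input_gel_table)
    rejected <- attr(gels, "errors")
    if (nrow(rejected) > 0) {
      logs <- pipeline_log(config, logs, "read: rejected %d malformed row(s)",
                           nrow(rejected))
    }
    first <- !duplicated(gels$sample_id)
    series <- sample_series(
      timestamp = gels$timestamp[first],
      host_abundance = NA_real_, phage_T4 = NA_real_, phage_T7 = NA_real_
    )
  }

  ## ---- quantify: co-sorting correction, QC, pooling ----------------------
  ids <- unique(gels$sample_id)
  logs <- pipeline_log(config, logs, "quantify: %d samples, %d gels",
                       length(ids), nrow(gels))
  samples <- lapply(seq_along(ids), function(i) {
    sub <- gels[gels$sample_id == ids[i], ]
    has_control <- !is.na(sub$filtrate_polony_count)
    counts <- sub$polony_count
    mode <- config$cosort$mode
    if (mode == "empirical_subtraction" && all(has_control)) {
      counts <- correct_cosort_empirical(sub$polony_count,
                                         sub$filtrate_polony_count)
      mode_used <- "empirical_subtraction"
    } else {
      mode_used <- if (mode == "none") "none" else "factor"
    }
    pooled <- pool_replicates(sub, qc = config$qc, counts = counts)
    percent <- pooled$percent
    if (mode_used == "factor") {
      fam <- sub$phage_family[1]
      conc <- if (fam == "T4like") series$phage_T4[i] else series$phage_T7[i]
      if (!is.na(conc)) {
        percent <- correct_cosort_factor(percent, fam, conc, config$cosort)
      }
    }
    bc <- bootstrap_config(iterations = config$bootstrap$iterations,
                           level = config$bootstrap$level,
                           seed = derive_seed(config$seed, 5000 + i),
                           count_resampling = config$bootstrap$count_resampling)
    # bootstrap works on corrected counts; factor corrections rescale after
    scale <- if (pooled$percent > 0) percent / pooled$percent else 1
    adj <- bootstrap_adjust(pooled$polonies, pooled$cells,
                            model = config$efficiency, config = bc,
                            lod_polonies = config$qc$min_polonies)
    bounds <- infection_bounds(percent, config$efficiency)
    tibble::tibble(
      sample_id = ids[i],
      timestamp = sub$timestamp[1],
      phage_family = sub$phage_family[1],
      polonies = pooled$polonies, cells = pooled$cells,
      percent_raw = pooled$percent,
      percent_cosort_corrected = percent,
      qc_status = pooled$qc_status, censored = pooled$censored,
      lod_percent = pooled$lod_percent,
      cosort_mode = mode_used,
      percent_adjusted = adj$point * scale,
      ci_low = adj$ci[["lower"]] * scale, ci_high = adj$ci[["upper"]] * scale,
      bound_low = bounds[["lower"]], bound_high = bounds[["upper"]],
      n_boot = adj$n_boot, boot_seed = adj$seed
    )
  })
  samples <- dplyr::bind_rows(samples)
  # censored samples report the LOD value as a flagged upper limit
  samples$percent_reported <- ifelse(samples$censored,
                                     samples$lod_percent / weighted_efficiency(config$efficiency),
                                     samples$percent_adjusted)

  series$infected_percent <- samples$percent_reported[
    match(format(series$timestamp), format(samples$timestamp))]
  series$infected_per_ml <- infected_cells_per_ml(series$infected_percent,
                                                  series$host_abundance)

  ## ---- diel analysis ------------------------------------------------------
  logs <- pipeline_log(config, logs, "diel: rhythmicity + day/night contrast")
  diel <- list()
  rhythm_vars <- c("infected_percent", "host_abundance", "phage_T4", "phage_T7")
  diel$rhythmicity <- dplyr::bind_rows(lapply(rhythm_vars, function(v) {
    vals <- series[[v]]
    if (all(is.na(vals))) return(NULL)
    rt <- rhythmicity_test(vals, series$time_h, period = 24,
                           n_permutations = config$n_permutations,
                           seed = derive_seed(config$seed, 7000 + match(v, rhythm_vars)))
    tibble::tibble(variable = v, period_h = 24, p_value = rt$p_value,
                   amplitude = rt$amplitude, peak_h = rt$peak_h,
                   n_permutations = rt$n_permutations, seed = rt$seed)
  }))
  if (!all(is.na(series$infected_percent))) {
    dn <- day_night_ratio(series$infected_percent, series$clock_h,
                          config$windows)
    diel$day_night <- dn
  }
  if (!all(is.na(series$host_abundance))) {
    diel$budget <- nightly_budget(series$host_abundance, series$time_h,
                                  series$clock_h,
                                  dusk_h = if (!is.null(config$sim)) config$sim$dusk_h else 18,
                                  dawn_h = if (!is.null(config$sim)) config$sim$dawn_h else 6)
  }

  ## ---- ecology -------------------------------------------------------------
  logs <- pipeline_log(config, logs, "ecology: encounters, mortality, turnover")
  host_mean <- mean(series$host_abundance, na.rm = TRUE)
  t4_mean <- mean(series$phage_T4, na.rm = TRUE)
  inst_range <- range(samples$percent_reported[!samples$censored])
  mort_model <- config$mortality
  if (is.null(mort_model)) {
    mort_model <- mortality_model(instantaneous_range = inst_range)
  }
  beta <- config$encounter$beta
  enc <- if (!is.na(t4_mean)) per_cell_encounter_rate(beta, t4_mean) else NULL
  ecology <- list(beta = beta, mortality_model = mort_model)
  if (!is.null(enc) && !is.na(host_mean)) {
    encounters <- population_daily_encounters(enc$rate_per_day, host_mean)
    mort <- daily_mortality_bounds(mort_model)
    cyc <- cycles_per_day(mort_model$latent_period_h, mort_model$cycles_range)
    daily_inf <- infected_cells_per_ml(mort, host_mean)
    ecology <- c(ecology, list(
      encounter_interval_h = enc$interval_h,
      per_cell_rate_per_day = enc$rate_per_day,
      encounters_per_ml_day = encounters,
      max_daily_mortality_percent = max_daily_mortality(encounters, host_mean),
      cycles_per_day = cyc,
      mortality_bounds_percent = mort,
      fraction_encounters_infective_percent = c(
        low = fraction_encounters_infective(daily_inf[["low"]], encounters),
        high = fraction_encounters_infective(daily_inf[["high"]], encounters)),
      turnover_days = c(
        slow = phage_turnover_time(turnover_model(
          standing_stock = config$turnover$standing_stock,
          burst_size = config$turnover$burst_size,
          lysed_per_cycle = config$turnover$lysed_per_cycle,
          cycles_per_day = mort_model$cycles_range[1])),
        fast = phage_turnover_time(turnover_model(
          standing_stock = config$turnover$standing_stock,
          burst_size = config$turnover$burst_size,
          lysed_per_cycle = config$turnover$lysed_per_cycle,
          cycles_per_day = mort_model$cycles_range[2])))
    ))
  }

  ## ---- summary -------------------------------------------------------------
  emodel <- config$efficiency
  summary <- list(
    seed = config$seed,
    n_samples = nrow(samples),
    mean_infection_percent = mean(samples$percent_reported),
    infection_range_percent = as.list(stats::setNames(inst_range,
                                                      c("low", "high"))),
    bounds_ratio = max(emodel$efficiencies) / min(emodel$efficiencies),
    night_day_ratio = if (!is.null(diel$day_night)) diel$day_night$ratio,
    rhythmicity_p_infection = if (!is.null(diel$rhythmicity)) {
      p <- diel$rhythmicity$p_value[diel$rhythmicity$variable == "infected_percent"]
      if (length(p) == 1) p
    },
    mortality_bounds_percent = if (!is.null(ecology$mortality_bounds_percent)) {
      as.list(ecology$mortality_bounds_percent)
    },
    encounter_interval_h = ecology$encounter_interval_h,
    encounters_per_ml_day = ecology$encounters_per_ml_day,
    fraction_encounters_infective_percent =
      if (!is.null(ecology$fraction_encounters_infective_percent)) {
        as.list(ecology$fraction_encounters_infective_percent)
      },
    turnover_days = if (!is.null(ecology$turnover_days)) {
      as.list(ecology$turnover_days)
    }
  )
  summary <- summary[!vapply(summary, is.null, logical(1))]

  ## ---- write ---------------------------------------------------------------
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$out_dir, f)
    write_gel_table(gels, out("gels.csv"), qc = config$qc)
    readr::write_csv(samples, out("quantify.csv"))
    sr <- series
    sr$timestamp <- format(sr$timestamp, "%Y-%m-%dT%H:%M:%S%z")
    readr::write_csv(sr, out("series.csv"))
    if (!is.null(truth)) {
      tr <- truth
      tr$timestamp <- format(tr$timestamp, "%Y-%m-%dT%H:%M:%S%z")
      readr::write_csv(tr, out("ground_truth.csv"))
    }
    if (!is.null(diel$rhythmicity)) {
      readr::write_csv(diel$rhythmicity, out("diel.csv"))
    }
    eco_flat <- tibble::tibble(
      quantity = c("encounter_interval_h", "encounters_per_ml_day",
                   "max_daily_mortality_percent", "mortality_low_percent",
                   "mortality_high_percent", "turnover_days_slow",
                   "turnover_days_fast"),
      value = c(ecology$encounter_interval_h %||% NA,
                ecology$encounters_per_ml_day %||% NA,
                ecology$max_daily_mortality_percent %||% NA,
                ecology$mortality_bounds_percent[["low"]] %||% NA,
                ecology$mortality_bounds_percent[["high"]] %||% NA,
                ecology$turnover_days[["slow"]] %||% NA,
                ecology$turnover_days[["fast"]] %||% NA)
    )
    readr::write_csv(eco_flat, out("ecology.csv"))
    jsonlite::write_json(summary, out("summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(logs, out("pipeline.log"))
    logs <- pipeline_log(config, logs, "wrote outputs to %s", config$out_dir)
  }

  invisible(list(samples = samples, series = series, diel = diel,
                 ecology = ecology, summary = summary, log = logs,
                 truth = truth))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
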