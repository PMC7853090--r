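# Fixture builders shared across test files. Everything is generated in code;
# no data files.

# n gels for one sample, all passing QC by construction
make_gels <- function(polonies, cells, filtrate = NA, sample_id = "s1",
                      family = "T4like") {
  dplyr::bind_rows(lapply(seq_along(polonies), function(i) {
    gel_assay(polonies[i], cells[i],
              filtrate_polony_count = if (length(filtrate) == 1) filtrate else filtrate[i],
              phage_family = family, replicate_id = paste0("r", i),
              sample_id = sample_id)
  }))
}

# regular 4-hourly timestamps over n_days, first sample at start_clock hours
make_times <- function(n_days = 7, interval = 4, start_clock = 6) {
  t0 <- as.POSIXct("2015-07-26 00:00:00", tz = "UTC") + start_clock * 3600
  n <- n_days * 24 / interval
  list(
    timestamp = t0 + (seq_len(n) - 1) * interval * 3600,
    time_h = (seq_len(n) - 1) * interval,
    clock_h = (start_clock + (seq_len(n) - 1) * interval) %% 24
  )
}

# a pure 24-h cosine with optional noise, peaking at `peak_clock`
make_cosine <- function(time_h, clock_start = 6, mean = 1, amplitude = 0.5,
                        peak_clock = 22, noise_sd = 0, seed = 1) {
  clock <- clock_start + time_h
  y <- mean + amplitude * cos(2 * pi * (clock - peak_clock) / 24)
  if (noise_sd > 0) {
    y <- y + dielphage:::with_seed(seed, stats::rnorm(length(y), 0, noise_sd))
  }
  y
}

# write a small gel-table CSV and return its path
write_gel_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  header <- "sample_id,timestamp_iso8601,phage_family,cells_loaded,polony_count,filtrate_polony_count,replicate_id"
  writeLines(c(header, rows), path)
  path
}
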