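#' @keywords internal
"_PACKAGE"

## internal helpers shared across modules

# Run `code` under a fixed RNG seed, restoring the caller's RNG state on exit.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Derive a stream-specific child seed from a base seed; stays below 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset * 7919 + 1) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero_lower = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stopf("`%s` must be a single non-missing number", name)
  }
  lo_ok <- if (allow_zero_lower) x >= lower else x > lower
  if (!lo_ok || x > upper) {
    stopf("`%s` = %g is outside [%s, %g]", name,
          x, if (allow_zero_lower) format(lower) else paste0(">", lower), upper)
  }
  invisible(x)
}

#' Report-formatting helpers for comparison with back-of-envelope values
#'
#' Rounding used when quoting results in summaries: percents to 2 significant
#' figures, durations in days to the nearest integer, burst sizes to the
#' nearest 50 virions, encounter totals to 1 significant figure. These live
#' outside the arithmetic: every computation returns full precision and these
#' are applied only when formatting a report.
#'
#' @param x numeric value to format.
#' @return the rounded numeric value.
#' @examples
#' report_percent(43.75)   # 44
#' report_days(22.9)       # 23
#' report_burst(152)       # 150
#' report_encounters(71111) # 70000
#' @name report-format
NULL

#' @rdname report-format
#' @export
report_percent <- function(x) signif(x, 2)

#' @rdname report-format
#' @export
report_days <- function(x) round(x)

#' @rdname report-format
#' @export
report_burst <- function(x) 50 * round(x / 50)

#' @rdname report-format
#' @export
report_encounters <- function(x) signif(x, 1)
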