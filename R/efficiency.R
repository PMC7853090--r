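## Detection-efficiency adjustment.
##
## The polony assay does not detect every infected cell: the probability that
## an infected cell yields a polony rises through the infection cycle, from
## low before phage genome replication to near-maximal after it. Field
## populations contain cells at every stage, so measured percent infection is
## biased low. The adjustment models detection with three stage bins
## (pre-replication, during replication, post-replication) whose efficiencies
## are weighted by the relative duration of each stage within the latent
## period.

#' Stage-binned detection-efficiency model
#'
#' @param efficiencies Three detection efficiencies (fractions in (0, 1\]) for
#'   the pre-replication, during-replication and post-replication stages.
#'   Defaults 0.25, 0.55, 0.86, from infection time-course experiments with
#'   cultured cyanophage-picocyanobacteria systems. Must be non-decreasing:
#'   detection improves as the infection advances.
#' @param weights Three non-negative stage weights summing to 1: the relative
#'   duration of each stage within the latent period. Default
#'   `c(2.5, 2.5, 2.9)/7.9`, stage durations in hours over a 7.9-h mean
#'   latent period.
#' @return An `efficiency_model` list with elements `efficiencies` and
#'   `weights`.
#' @export
efficiency_model <- function(efficiencies = c(0.25, 0.55, 0.86),
                             weights = c(2.5, 2.5, 2.9) / 7.9) {
  if (length(efficiencies) != 3 || length(weights) != 3) {
    stopf("`efficiencies` and `weights` must each have length 3")
  }
  if (any(efficiencies <= 0) || any(efficiencies > 1)) {
    stopf("each efficiency must lie in (0, 1]")
  }
  if (is.unsorted(efficiencies)) {
    stopf("efficiencies must be non-decreasing across infection stages")
  }
  if (any(weights < 0)) stopf("stage weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-9) {
    stopf("stage weights must sum to 1 (got %.12f)", sum(weights))
  }
  structure(list(efficiencies = as.double(efficiencies),
                 weights = weights / sum(weights)),
            class = "efficiency_model")
}

#' Bootstrap configuration for efficiency adjustment
#'
#' @param iterations Number of bootstrap iterations (default 10,000; at least
#'   100).
#' @param level Confidence level for the percentile interval (default 0.95).
#' @param seed Integer seed; identical seeds give bit-identical results.
#' @param count_resampling `"poisson"` (default; polony counts are rare-event
#'   counts relative to cells screened), `"binomial"`, or `"none"` to hold
#'   the observed count fixed and propagate only stage-mix uncertainty.
#' @return A `bootstrap_config` list.
#' @export
bootstrap_config <- function(iterations = 10000, level = 0.95, seed = 1L,
                             count_resampling = c("poisson", "binomial", "none")) {
  count_resampling <- match.arg(count_resampling)
  check_number(iterations, "iterations", lower = 100)
  if (level <= 0 || level >= 1) stopf("`level` must lie in (0, 1)")
  structure(list(iterations = as.integer(iterations), level = level,
                 seed = as.integer(seed), count_resampling = count_resampling),
            class = "bootstrap_config")
}

#' Latent-period-weighted mean detection efficiency
#'
#' @param model An [efficiency_model()].
#' @return The weighted mean efficiency, in (0, 1\].
#' @export
#' @examples
#' weighted_efficiency(efficiency_model(weights = rep(1, 3) / 3))  # 0.5533...
weighted_efficiency <- function(model) {
  stopifnot(inherits(model, "efficiency_model"))
  sum(model$weights * model$efficiencies)
}

#' Point adjustment of percent infection for detection efficiency
#'
#' Divides the measured percent by the weighted mean efficiency; the adjusted
#' estimate is never smaller than the raw one.
#'
#' @param raw_percent Measured (corrected-for-co-sorting) percent infection.
#' @param model An [efficiency_model()].
#' @return Adjusted percent infection.
#' @export
adjust_point <- function(raw_percent, model = efficiency_model()) {
  if (any(raw_percent < 0)) stopf("`raw_percent` must be non-negative")
  raw_percent / weighted_efficiency(model)
}

#' Synchronisation bounds on percent infection
#'
#' If every infected cell were in the latest stage (best detected), the raw
#' value divided by the maximum efficiency is a lower bound on true
#' infection; if every cell were pre-replication (worst detected), dividing
#' by the minimum efficiency gives an upper bound. With the default bins the
#' upper/lower ratio is 0.86/0.25 = 3.44.
#'
#' @param raw_percent Measured percent infection.
#' @param model An [efficiency_model()].
#' @return Named numeric vector `c(lower, upper)` in percent.
#' @export
infection_bounds <- function(raw_percent, model = efficiency_model()) {
  if (any(raw_percent < 0)) stopf("`raw_percent` must be non-negative")
  c(lower = raw_percent / max(model$efficiencies),
    upper = raw_percent / min(model$efficiencies))
}

#' Bootstrap adjustment of pooled polony counts for stage uncertainty
#'
#' Propagates two uncertainties into the adjusted percent: counting noise on
#' the polony total and ignorance of the infection-stage composition. Each
#' iteration (a) resamples the polony count (Poisson at the observed count by
#' default), (b) assigns the resampled polonies to stages by a multinomial
#' draw with probabilities proportional to `weight * efficiency` - detected
#' polonies are detections, so their stage mix is biased toward well-detected
#' late stages - and (c) inverts the thinning stage-by-stage:
#' `100/cells * sum(stage count / stage efficiency)`. The point estimate is
#' the bootstrap median and the interval is the central percentile interval.
#'
#' @param polonies Pooled (co-sort-corrected) polony count for the sample.
#' @param cells Pooled number of cells screened, > 0.
#' @param model An [efficiency_model()].
#' @param config A [bootstrap_config()].
#' @param lod_polonies Polony count defining the limit of detection, used for
#'   the censored upper bound when `polonies` is 0 (default 5).
#' @return A list: `point` (median adjusted percent), `ci` (lower, upper),
#'   `level`, `n_boot`, `seed`, `zero_count` flag, and `replicates` summary
#'   (mean, sd, quartiles of the bootstrap distribution).
#' @export
bootstrap_adjust <- function(polonies, cells, model = efficiency_model(),
                             config = bootstrap_config(), lod_polonies = 5) {
  check_number(polonies, "polonies", lower = 0)
  check_number(cells, "cells", lower = 0, allow_zero_lower = FALSE)
  stopifnot(inherits(model, "efficiency_model"),
            inherits(config, "bootstrap_config"))

  e <- model$efficiencies
  w <- model$weights
  alpha <- (1 - config$level) / 2

  if (polonies == 0) {
    # nothing detected: censored at the LOD, upper bound assumes the least
    # detectable (pre-replication) composition at the LOD count
    upper <- 100 * lod_polonies / cells / min(e)
    return(list(point = 0, ci = c(lower = 0, upper = upper),
                level = config$level, n_boot = config$iterations,
                seed = config$seed, zero_count = TRUE,
                replicates = c(mean = 0, sd = 0,
                               q25 = 0, q50 = 0, q75 = 0)))
  }

  draws <- with_seed(config$seed, {
    b <- config$iterations
    n_star <- switch(config$count_resampling,
      poisson = stats::rpois(b, polonies),
      binomial = stats::rbinom(b, size = cells, prob = polonies / cells),
      none = rep.int(polonies, b)
    )
    # multinomial over 3 stages via sequential binomials (vectorised over b)
    p <- w * e
    p <- p / sum(p)
    n1 <- stats::rbinom(b, n_star, p[1])
    n2 <- stats::rbinom(b, n_star - n1, p[2] / (p[2] + p[3]))
    n3 <- n_star - n1 - n2
    100 / cells * (n1 / e[1] + n2 / e[2] + n3 / e[3])
  })

  qs <- stats::quantile(draws, c(alpha, 0.25, 0.5, 0.75, 1 - alpha),
                        names = FALSE, type = 7)
  list(
    point = qs[3],
    ci = c(lower = qs[1], upper = qs[5]),
    level = config$level,
    n_boot = config$iterations,
    seed = config$seed,
    zero_count = FALSE,
    replicates = c(mean = mean(draws), sd = stats::sd(draws),
                   q25 = qs[2], q50 = qs[3], q75 = qs[4])
  )
}
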