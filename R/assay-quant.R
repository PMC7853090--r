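## Quantification of percent infection from polony gel assays.
##
## A "gel assay" is one polyacrylamide gel: a known number of sorted cells
## screened for intracellular phage DNA, scored as a polony count. Free
## viruses co-sorted with cells add false-positive polonies; they are removed
## either by subtracting a <0.2 um filtrate control run under the same
## conditions, or by an empirical correction factor applied when ambient
## phage concentrations exceed the co-sorting threshold.

PHAGE_FAMILIES <- c("T4like", "T7like")

#' Construct a single gel assay record
#'
#' @param polony_count Non-negative integer count of polonies scored on the
#'   gel (infected cells plus any co-sorted free viruses).
#' @param cells_loaded Positive integer number of sorted cells embedded in the
#'   gel (typically 8,000-10,000 for field samples).
#' @param filtrate_polony_count Optional non-negative integer: polonies counted
#'   in a gel run on the <0.2 um filtrate of the sorted cells, measuring the
#'   co-sorted free-virus contribution. `NA` when no control was run.
#' @param phage_family `"T4like"` or `"T7like"`.
#' @param replicate_id Label distinguishing replicate gels of one sample.
#' @param sample_id Optional sample label.
#' @return A one-row tibble with class `"gel_table"`.
#' @export
#' @examples
#' gel_assay(152, 8000)
gel_assay <- function(polony_count, cells_loaded, filtrate_polony_count = NA,
                      phage_family = "T4like", replicate_id = "r1",
                      sample_id = "s1") {
  tbl <- tibble::tibble(
    sample_id = as.character(sample_id),
    phage_family = as.character(phage_family),
    replicate_id = as.character(replicate_id),
    cells_loaded = as.double(cells_loaded),
    polony_count = as.double(polony_count),
    filtrate_polony_count = as.double(filtrate_polony_count)
  )
  validate_gel_table(tbl)
}

validate_gel_table <- function(tbl) {
  required <- c("sample_id", "phage_family", "replicate_id",
                "cells_loaded", "polony_count", "filtrate_polony_count")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    stopf("gel table is missing column(s): %s", paste(missing, collapse = ", "))
  }
  if (any(is.na(tbl$cells_loaded)) || any(tbl$cells_loaded <= 0)) {
    stopf("`cells_loaded` must be a positive cell count for every gel")
  }
  if (any(is.na(tbl$polony_count)) || any(tbl$polony_count < 0)) {
    stopf("`polony_count` must be a non-negative count for every gel")
  }
  bad_fam <- !tbl$phage_family %in% PHAGE_FAMILIES
  if (any(bad_fam)) {
    stopf("unknown phage family: %s (expected one of %s)",
          paste(unique(tbl$phage_family[bad_fam]), collapse = ", "),
          paste(PHAGE_FAMILIES, collapse = ", "))
  }
  fc <- tbl$filtrate_polony_count
  if (any(!is.na(fc) & fc < 0)) {
    stopf("`filtrate_polony_count` must be non-negative where present")
  }
  class(tbl) <- unique(c("gel_table", class(tbl)))
  tbl
}

#' Co-sorting correction policy
#'
#' Free cyanophages above an empirically determined ambient concentration are
#' carried along in the sorted-cell stream and form false-positive polonies.
#' When no filtrate control is available, percent infection is multiplied by a
#' family-specific factor whenever the ambient free-phage concentration
#' exceeds that family's threshold.
#'
#' @param threshold_T7,threshold_T4 Co-sorting thresholds, viruses per ml
#'   (defaults 5e5 and 3e5).
#' @param factor_T7,factor_T4 Multiplicative correction factors in (0, 1]
#'   (defaults 0.918 and 0.805).
#' @param mode `"empirical_subtraction"`, `"factor"`, or `"none"`. In the
#'   pipeline, empirical subtraction takes precedence when a filtrate control
#'   was measured.
#' @return A `cosort_policy` list.
#' @export
cosort_policy <- function(threshold_T7 = 5e5, threshold_T4 = 3e5,
                          factor_T7 = 0.918, factor_T4 = 0.805,
                          mode = c("empirical_subtraction", "factor", "none")) {
  mode <- match.arg(mode)
  check_number(threshold_T7, "threshold_T7", lower = 0, allow_zero_lower = FALSE)
  check_number(threshold_T4, "threshold_T4", lower = 0, allow_zero_lower = FALSE)
  for (f in c(factor_T7 = factor_T7, factor_T4 = factor_T4)) {
    if (f <= 0 || f > 1) stopf("co-sort factors must lie in (0, 1]")
  }
  structure(list(threshold_T7 = threshold_T7, threshold_T4 = threshold_T4,
                 factor_T7 = factor_T7, factor_T4 = factor_T4, mode = mode),
            class = "cosort_policy")
}

#' Per-gel quality-control policy
#'
#' Gels with too few polonies sit below the limit of accurate quantification;
#' gels with too many have overlapping polonies and cannot be counted
#' reliably.
#'
#' @param min_polonies Lower QC bound (default 5, matching a 0.05% limit of
#'   detection at 10,000 cells per gel).
#' @param max_polonies Upper QC bound (default 2000).
#' @return A `gel_qc_policy` list.
#' @export
gel_qc_policy <- function(min_polonies = 5, max_polonies = 2000) {
  if (!(min_polonies > 0 && min_polonies < max_polonies)) {
    stopf("require 0 < min_polonies < max_polonies")
  }
  structure(list(min_polonies = min_polonies, max_polonies = max_polonies),
            class = "gel_qc_policy")
}

#' Raw percent infection of one gel
#'
#' Percent infection before any correction: 100 x polonies / input cells.
#'
#' @param polony_count Polony count(s); vectorised.
#' @param cells_loaded Input cell count(s) per gel, > 0.
#' @return Percent infection in \[0, 100+\] (co-sorted viruses can push a raw
#'   value above the infected-cell fraction).
#' @export
#' @examples
#' raw_percent_infection(5, 10000)   # 0.05, the assay's detection limit
raw_percent_infection <- function(polony_count, cells_loaded) {
  if (any(is.na(cells_loaded)) || any(cells_loaded <= 0)) {
    stopf("`cells_loaded` must be positive")
  }
  if (any(is.na(polony_count)) || any(polony_count < 0)) {
    stopf("`polony_count` must be non-negative")
  }
  100 * polony_count / cells_loaded
}

#' Empirical co-sorting correction by filtrate subtraction
#'
#' Subtracts the polonies attributable to co-sorted free viruses, measured in
#' a <0.2 um filtrate control gel, from the total polony count. A negative
#' difference is clipped to zero: counts are physical.
#'
#' @param polony_count Total polony count(s).
#' @param filtrate_polony_count Filtrate-control polony count(s); must be
#'   present (non-`NA`).
#' @return Corrected polony count(s), `max(polony - filtrate, 0)`.
#' @export
correct_cosort_empirical <- function(polony_count, filtrate_polony_count) {
  if (any(is.na(filtrate_polony_count))) {
    stopf(paste("filtrate control unavailable: no `filtrate_polony_count`;",
                "use correct_cosort_factor() for samples without a control"))
  }
  if (any(polony_count < 0) || any(filtrate_polony_count < 0)) {
    stopf("counts must be non-negative")
  }
  pmax(polony_count - filtrate_polony_count, 0)
}

#' Factor-based co-sorting correction
#'
#' When no filtrate control exists, percent infection is multiplied by the
#' family's correction factor if, and only if, the ambient free-phage
#' concentration exceeds the family's co-sorting threshold.
#'
#' @param percent Uncorrected percent infection (vectorised).
#' @param family Phage family per value: `"T4like"` or `"T7like"`.
#' @param free_phage_conc Ambient free-phage concentration, per ml.
#' @param policy A [cosort_policy()].
#' @return Corrected percent infection; never larger than the input.
#' @export
#' @examples
#' correct_cosort_factor(1.0, "T4like", 4e5)  # 0.805: above the 3e5 threshold
#' correct_cosort_factor(1.0, "T4like", 1e5)  # 1.0: below it
correct_cosort_factor <- function(percent, family, free_phage_conc,
                                  policy = cosort_policy()) {
  if (any(percent < 0) || any(free_phage_conc < 0)) {
    stopf("`percent` and `free_phage_conc` must be non-negative")
  }
  n <- max(length(percent), length(family), length(free_phage_conc))
  percent <- rep_len(percent, n)
  family <- rep_len(family, n)
  free_phage_conc <- rep_len(free_phage_conc, n)
  if (any(!family %in% PHAGE_FAMILIES)) {
    stopf("unknown phage family: %s",
          paste(setdiff(unique(family), PHAGE_FAMILIES), collapse = ", "))
  }
  threshold <- ifelse(family == "T4like", policy$threshold_T4, policy$threshold_T7)
  factor <- ifelse(family == "T4like", policy$factor_T4, policy$factor_T7)
  ifelse(free_phage_conc > threshold, percent * factor, percent)
}

#' Classify a gel against the QC bounds
#'
#' @param polony_count Polony count(s); vectorised.
#' @param policy A [gel_qc_policy()].
#' @return Character vector: `"below_loq"`, `"ok"`, or `"saturated"`.
#' @export
qc_gel <- function(polony_count, policy = gel_qc_policy()) {
  dplyr::case_when(
    polony_count < policy$min_polonies ~ "below_loq",
    polony_count > policy$max_polonies ~ "saturated",
    .default = "ok"
  )
}

#' Pool replicate gels of one sample
#'
#' Replicate gels screen different numbers of cells, so pooling is
#' count-based (sum of polonies over sum of cells), not a mean of per-gel
#' percents. Gels failing QC are excluded from the pool when at least one gel
#' passes; when every gel fails low, the sample is reported censored at the
#' limit of detection (`100 * min_polonies / total cells`, flagged) rather
#' than dropped, preserving time-series continuity.
#'
#' @param assays A gel table (rows are replicate gels of one sample and one
#'   phage family), e.g. built with [gel_assay()] and `dplyr::bind_rows()`.
#' @param qc A [gel_qc_policy()].
#' @param counts Optional corrected polony counts to pool instead of the raw
#'   `polony_count` column (e.g. after [correct_cosort_empirical()]).
#' @return A list: `percent` (pooled estimate), `polonies` and `cells`
#'   (pooled counts), `qc_status` (`"ok"`, `"below_loq"` or `"saturated"`),
#'   `censored` (logical), `lod_percent` (censoring value), `per_gel`
#'   (per-gel percents), and `range` (spread of per-gel percents).
#' @export
#' @examples
#' gels <- dplyr::bind_rows(gel_assay(50, 10000), gel_assay(60, 10000))
#' pool_replicates(gels)$percent  # 0.55
pool_replicates <- function(assays, qc = gel_qc_policy(), counts = NULL) {
  assays <- validate_gel_table(tibble::as_tibble(assays))
  if (nrow(assays) == 0) stopf("no quantifiable gel: empty assay list")
  if (length(unique(assays$sample_id)) > 1 ||
      length(unique(assays$phage_family)) > 1) {
    stopf("pool_replicates() expects gels from one sample and one phage family")
  }
  counts <- if (is.null(counts)) assays$polony_count else rep_len(counts, nrow(assays))
  status <- qc_gel(counts, qc)
  pass <- status == "ok"

  per_gel <- raw_percent_infection(counts, assays$cells_loaded)
  lod_percent <- 100 * qc$min_polonies / sum(assays$cells_loaded)

  if (any(pass)) {
    polonies <- sum(counts[pass])
    cells <- sum(assays$cells_loaded[pass])
    out_status <- "ok"
    censored <- FALSE
  } else if (all(status == "saturated")) {
    stopf("no quantifiable gel: all %d gel(s) saturated", nrow(assays))
  } else {
    # all gels below the limit of quantification: censor at the LOD
    polonies <- sum(counts)
    cells <- sum(assays$cells_loaded)
    out_status <- "below_loq"
    censored <- TRUE
  }

  list(
    percent = 100 * polonies / cells,
    polonies = polonies,
    cells = cells,
    qc_status = out_status,
    censored = censored,
    lod_percent = lod_percent,
    per_gel = per_gel,
    range = if (length(per_gel) > 1) diff(range(per_gel)) else 0
  )
}
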