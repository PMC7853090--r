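# dielphage

Quantifying viral infection of marine picocyanobacteria from single-cell
polony assays, and converting it into ecological rates.

In oligotrophic surface oceans, *Prochlorococcus* divides synchronously at
dusk yet its abundance is stable over weeks, so mortality must balance
division on a daily timescale. How much of that mortality do cyanophages
cause? Polony gel assays answer the first half directly: thousands of
flow-sorted cells are screened per gel for intracellular phage DNA, and
percent infection is the polony count over the input cells. `dielphage`
implements the full computational chain from those raw counts to daily
mortality:

1. **Assay quantification** — raw percent infection, co-sorted free-virus
   corrections (filtrate-control subtraction, or family-specific factors
   above the co-sorting thresholds), per-gel QC against the 5–2000 polony
   bounds, and count-pooled replicate gels with LOD censoring
   (`raw_percent_infection()`, `correct_cosort_empirical()`,
   `correct_cosort_factor()`, `qc_gel()`, `pool_replicates()`).
2. **Detection-efficiency adjustment** — infected cells are detected with
   stage-dependent efficiency (25 / 55 / 86% before, during and after
   phage genome replication). The measured percent is divided by the
   latent-period-weighted mean efficiency ē = Σ wᵢeᵢ, with bootstrap
   propagation of counting noise and stage-mix uncertainty, and
   synchronisation bounds from the two extreme stage compositions
   (`adjust_point()`, `bootstrap_adjust()`, `infection_bounds()`).
3. **Diel analysis** — a permutation harmonic-amplitude test for 24-h
   rhythmicity, night:day contrast over configurable clock windows, and
   the nightly production budget implied by synchronous division
   (`rhythmicity_test()`, `day_night_ratio()`, `nightly_budget()`).
4. **Ecological rates** — encounter-rate theory (β = 2πdD, or calibrated
   from an observed per-cell encounter interval), daily mortality bounds
   (instantaneous infection × infection cycles per day), phage
   standing-stock turnover, required burst sizes, and reconciliation of
   the encounter–infection gap across infectivity, adsorption and host
   resistance (`per_cell_encounter_rate()`, `daily_mortality_bounds()`,
   `phage_turnover_time()`, `reconcile_mechanisms()`).
5. **Synthetic campaigns** — a generator emulating a 7-day, 4-hourly
   Lagrangian field campaign with ground truth (host diel cycle, aperiodic
   phages, a night-doubling infected fraction, stage-resolved assay
   simulation), so every estimator is validated by parameter recovery
   (`sim_config()`, `generate_campaign()`, `end_to_end_recovery()`).

The methods vignette (`vignettes/diel-infection-methods.Rmd`) documents
the models, defaults and design choices in detail.

## Worked example

Two replicate gels from one sample, with filtrate controls:

```r
library(dielphage)

gels <- dplyr::bind_rows(
  gel_assay(68, 9200, filtrate_polony_count = 0),
  gel_assay(81, 9800, filtrate_polony_count = 1))

pooled <- pool_replicates(gels)
pooled$percent
#> [1] 0.7842105

adj <- bootstrap_adjust(pooled$polonies, pooled$cells,
                        config = bootstrap_config(iterations = 10000, seed = 1))
sprintf("adjusted %.2f%% (95%% CI %.2f-%.2f)", adj$point, adj$ci[1], adj$ci[2])
#> [1] "adjusted 1.38% (95% CI 1.13-1.64)"

infection_bounds(pooled$percent)
#>     lower     upper
#> 0.9118727 3.1368421
```

0.78% of screened cells carried phage DNA; correcting for
stage-dependent detection nearly doubles that to 1.38%, with hard
synchronisation bounds 0.91–3.14% (all infections late vs all early in the
cycle). Converting a 0.35–1.6% instantaneous infection range into daily
rates:

```r
daily_mortality_bounds(mortality_model(latent_period_h = 7.9,
                                       instantaneous_range = c(0.35, 1.6)))
#>  low high
#> 0.35  4.8
```

i.e. with a 7.9-h latent period (1–3 lytic cycles per day), viruses kill
0.35–4.8% of the population daily. A full synthetic-campaign recovery:

```r
rec <- end_to_end_recovery(sim_config(seed = 1))
c(true = rec$mean_true_percent, recovered = rec$mean_recovered_percent,
  night_day = rec$night_day_ratio, coverage = rec$ci_coverage)
#>      true recovered night_day  coverage
#>     0.777     0.767      1.99      0.95
```

The pipeline recovers the campaign's mean infected fraction within a few
percent, the constructed 2-fold night:day contrast, and 95% interval
coverage of the per-timepoint truth.

The whole chain also runs as one configured pipeline —
`run_pipeline(pipeline_config(sim = sim_config(seed = 1), out_dir = "out"))`
— writing per-stage CSVs, a JSON summary of the headline numbers and a
log; `inst/cli/dielphage.R` wraps this for shell use with subcommands
`simulate`, `quantify`, `adjust`, `diel`, `ecology` and `run-all`.

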