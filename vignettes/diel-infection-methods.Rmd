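---
title: "From polony counts to daily viral mortality: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From polony counts to daily viral mortality: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dielphage)
```

## The measurement and its biases

A polony gel assay screens a known number of flow-sorted cyanobacterial
cells (typically 8,000–10,000 per gel for field samples) for intracellular
cyanophage DNA; each infected cell that amplifies forms one polony. The raw
estimate of the instantaneous infected fraction is simply

$$\hat{p}_\text{raw} = 100 \times \frac{P}{N_\text{gel}} \;\; [\%],$$

with $P$ polonies and $N_\text{gel}$ input cells. Two systematic biases sit
on top of the counting noise:

1. **Co-sorted free viruses.** Free phage particles carried along in the
   sorted-cell stream amplify just like infected cells. Where a
   <0.2&nbsp;µm filtrate of the sorted cells was run as a control gel, its
   polony count is subtracted (`correct_cosort_empirical()`); a negative
   difference is clipped to zero because counts are physical. Without a
   control, percent infection is multiplied by a family-specific factor
   (0.805 for T4-like, 0.918 for T7-like) whenever the ambient free-phage
   concentration exceeds the family's co-sorting threshold (3×10⁵ and
   5×10⁵ ml⁻¹ respectively; `correct_cosort_factor()`). When both routes
   are available, empirical subtraction takes precedence: it is a direct
   measurement under the same sorting conditions. The filtrate control is
   treated as matched in effective volume to the cell gel — controls are run
   under the same conditions as the sorted cells — so no volume scaling is
   applied before subtraction.

2. **Stage-dependent detection.** The probability that an infected cell
   yields a polony rises through the lytic cycle: roughly 25% before phage
   genome replication, 55% during it, and 86% after, from infection
   time-courses in cultured host–phage systems. Field populations contain a
   mixture of stages, so the raw percent is divided by a latent-period
   weighted mean efficiency $\bar e = \sum_i w_i e_i$
   (`adjust_point()`).

Per-gel quality control marks gels with fewer than 5 polonies as below the
limit of accurate quantification and gels above 2,000 as saturated
(overlapping polonies). The default lower bound of 5 matches the assay's
0.05% detection limit at 10,000 cells per gel; both bounds are
configurable in `gel_qc_policy()`. Replicate gels are pooled as
$100\sum P / \sum N$, never as a mean of per-gel percents, because
replicates screen different cell numbers. A sample whose gels all fail low
is reported censored at the limit of detection
($100 \times \text{min polonies} / \sum N$, flagged) rather than dropped,
so the diel time series keeps its spacing; `pool_replicates()` returns both
the pooled ratio and the censoring value so callers can choose.

## Stage weights

The three efficiency bins need duration weights. The package's default is
the stage durations as fractions of the 7.9-h mean T4-like latent period,
$(2.5, 2.5, 2.9)/7.9 \approx (0.316, 0.316, 0.367)$: equal pre- and
during-replication phases and a slightly longer post-replication phase,
reconstructed from the phase structure of the culture infection
time-courses. Weights are a mandatory, documented field of
`efficiency_model()` precisely because they are a modelling choice rather
than a measured constant; any analysis can substitute its own.

## Bootstrap uncertainty

`bootstrap_adjust()` propagates two uncertainties that the point adjustment
ignores. Each of the (default 10,000) iterations:

a. resamples the pooled polony count from a Poisson law at the observed
   count — infection is rare relative to the cells screened, so Poisson and
   binomial resampling are practically identical (a binomial mode is
   available via `bootstrap_config(count_resampling = "binomial")`, and
   `"none"` disables count resampling for stage-mix-only intervals);
b. draws a stage composition for the resampled polonies from a multinomial
   with probabilities proportional to $w_i e_i$. The bias toward late
   stages is deliberate: observed polonies are *detections*, and detection
   is more likely late in the cycle;
c. inverts the thinning stage by stage,
   $\hat p = \frac{100}{N}\sum_i n_i / e_i$.

The reported point is the bootstrap median and the interval is the central
percentile interval (no bias correction — the simplest defensible choice,
and the one easiest to reason about). With this scheme
$E[\hat p] = \hat p_\text{raw} / \bar e$, so the bootstrap median converges
to the deterministic adjustment as counts grow; the test suite checks this
at 10⁵ polonies within 2%. A zero count returns a flagged degenerate
interval from 0 to the efficiency-adjusted limit of detection. Everything
is reproducible bit-for-bit under a fixed seed.

Alongside the stage-mixture adjustment, `infection_bounds()` reports the
two perfectly synchronised extremes — all infections pre-replication
(divide by 0.25, upper bound) or all post-replication (divide by 0.86,
lower bound). Their ratio, 0.86/0.25 = 3.44 (“3.4-fold”), is the maximal
spread that stage ignorance can induce.

## Rhythmicity testing

`rhythmicity_test()` is a permutation harmonic-amplitude test: fit a single
sinusoid of the candidate period (24 h) by least squares, take its
amplitude as the statistic, and build the null by permuting values across
the fixed sampling times. The p-value uses the add-one permutation
estimator, so $p \in (0, 1]$ and the test is exact-level by construction.
This is a deliberate stand-in for rank-based rhythmicity packages used in
field studies: it is self-contained, assumption-light, and calibrated by
construction, but it does not attempt to reproduce those packages'
p-values, settings, or multi-period grids. Requirements: at least two full
periods of data and four samples per period; fewer is an error, not a
warning, because a sub-2-cycle series cannot distinguish rhythm from
trend.

Day–night contrast (`day_night_ratio()`) compares window means with the
night window 18:00–02:00 and day window 06:00–14:00 by default. Clock
windows are half-open $[\text{start}, \text{end})$ in local solar time and
may wrap midnight; with the default windows no sample can fall on a shared
boundary. Missing samples inside a window simply reduce that window's
sample count, which the return value reports. `nightly_budget()` closes
the production ledger per night: expected new cells (division fraction ×
pre-dusk abundance) equal the observed post-dusk increase plus the implied
loss, exactly.

## Ecological rates

Encounter-rate theory for a diffusing virus and a spherical host gives the
kernel $\beta = 2\pi d D$ (cm³ s⁻¹). Because the physical parameters
behind any particular field estimate are usually reported only indirectly,
the default `encounter_model()` is *calibrated*: $\beta$ is back-computed
from a per-cell encounter interval of 54 h at 3.3×10⁵ phages ml⁻¹, and
kernel mode exists for sensitivity analysis. The calibration and the
per-cell rate are exact inverses (tested to machine precision). Pure
diffusion is assumed — no advective (Sherwood-number) enhancement — which
makes the encounter total conservative.

From there the arithmetic is deliberately transparent: population
encounters per day (rate × host concentration); the mortality ceiling if
every encounter killed (encounters / hosts, capped at 100%); daily
mortality bounds as instantaneous infection × completed infection cycles
per day, with cycles = ⌊24 h / latent period⌋ clamped to 1–3 (7.9 h →
3 cycles); the standing-stock turnover time (stock / (burst × lysed per
cycle × cycles)); and the burst size required to explain an observed phage
increase. `reconcile_mechanisms()` expresses the gap between encounters
and realised infections as the single-mechanism fractions (infectivity,
adsorption, susceptibility — all equal to the infection:encounter ratio;
host resistance is the complement) and as the balanced three-mechanism
solution, the cube root of that ratio. The observed daily-infection input
is an argument, not a constant, because it is an empirical quantity.

Report rounding (percents to 2 significant figures, days to integers,
bursts to the nearest 50, encounter totals to 1 significant figure) is
implemented as explicit `report_*()` formatters and never inside the
arithmetic, so derived quantities always compose at full precision. Where
a headline ratio is defined against a *reported* (rounded) denominator —
e.g. infective-encounter fractions against “70,000 encounters” — the
rounding is applied once, visibly, at the call site.

## The synthetic campaign

`generate_campaign()` emulates a 7-day Lagrangian surface-ocean campaign
sampled every 4 h, with a full ground-truth channel so that every pipeline
stage can be validated by parameter recovery:

* **True infected fraction**: a smoothed square wave, not a sinusoid — a
  day plateau, a 4-h linear rise through late afternoon reaching the
  night plateau (ratio × day level, default 2) at dusk, and a linear
  pre-dawn drop from the end of the peak window (02:00) to dawn. Field
  observations describe exactly this plateau-rise-plateau-drop phenology
  (a roughly 2-fold rise toward dusk, maximal infection late night, a
  ~2-fold drop between 02:00 and 06:00), and a plateau waveform pins the
  day:night contrast independently of the window means in a way a sinusoid
  does not. The waveform is scaled so its time average equals the
  configured mean (default 0.79%), then multiplied by lognormal process
  noise (CV 0.05).
* **Host abundance**: mean 1.75×10⁵ ± 0.55×10⁵ cells ml⁻¹ (spanning the
  observed 1.2–2.3×10⁵ range) with discrete phenomenological phases —
  night rise from synchronous dusk division, a small pre-dawn loss pulse,
  daytime decline — rather than a continuous growth–loss ODE: the minimal
  parameterisation that reproduces synchronous-division phenomenology.
* **Free phages**: aperiodic by construction (a latent AR(1) squashed into
  the observed ranges, 2.7–4.1×10⁵ ml⁻¹ for T4-like and 1.7–3.8×10⁴ ml⁻¹
  for T7-like), matching the observation that standing stocks show no diel
  cycle.
* **Stage occupancy**: proportional to stage durations at steady state,
  shifted early-stage-heavy while infection is rising (and late-heavy
  while falling) through a single phasing parameter (default 0.3, a
  moderate shift chosen so the detected mix remains within the efficiency
  model's reach).
* **Assays**: per gel, cells uniform in 8,000–10,000 (2 gels per sample),
  truly infected cells binomial at the true fraction, stage split
  multinomial at the true occupancy, detection by per-stage binomial
  thinning, plus independent Poisson co-sort false polonies (default rate
  0; the filtrate control draws the same rate).

Everything is reproducible byte-for-byte under the mandatory seed, and the
truth channel is never written into the emitted sample series.

What the generator does *not* emulate — and therefore what passing
recovery tests cannot certify — includes: advection and water-mass
exchange around the Lagrangian track; light-dependent infection kinetics;
multi-strain host and phage diversity (a single homogeneous susceptibility
is assumed); phage decay; and any coupling from infection back onto host
dynamics. Recovery results demonstrate that the estimators are consistent
under the stated noise model, not that the field values are correct.

## Numerical and testing choices

* Permutation p-values use the add-one estimator; 199–999 permutations in
  tests, which makes the 0.05 threshold exactly attainable.
* Bootstrap multinomial draws use sequential binomials, vectorised over
  iterations; quantiles are type-7.
* Seeds: every stochastic entry point takes a seed; internal stages derive
  child seeds with a fixed integer recurrence kept below 2³¹, and RNG
  state is always restored on exit.
* Test problem sizes: the CI-coverage simulation uses 500 synthetic assays
  of 10,000 cells at a true 1.0% infected fraction with 1,000-iteration
  bootstraps; the size calibration uses 500 white-noise series of 42
  samples with 199 permutations; end-to-end recovery runs 20 replicate
  default campaigns with 500-iteration bootstraps. These sizes give
  Monte-Carlo standard errors comfortably inside the asserted tolerances
  (±15% relative bias on the recovered mean, [1.6, 2.4] on the recovered
  night:day ratio, coverage ≥ 92% at the 95% level, test size within
  ±0.03 of α = 0.05).

## Known limitations

* The stage weights and the detected-stage multinomial are a declared
  reconstruction of how stage uncertainty should be propagated; both are
  isolated behind `efficiency_model()` and `bootstrap_config()` so
  alternatives are pluggable without touching callers.
* The efficiency bins are family-agnostic defaults even though
  pre-replication detection differs between T7-like and T4-like systems
  in culture (43% vs 11%); per-family models can be passed explicitly.
* The rhythmicity stand-in tests a single fixed period; it is not a
  substitute for multi-period or nonparametric waveform inference.
* Censored (all-gels-below-LOQ) samples enter the series at the
  efficiency-adjusted LOD value, which slightly biases window means upward
  in extremely low-infection regimes.
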