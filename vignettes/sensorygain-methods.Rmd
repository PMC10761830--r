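---
title: "Models and methods behind sensorygain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sensorygain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(sensorygain)
```

`sensorygain` analyses within-subject pharmacological experiments on sensory
cortex in which every unit — a neuron, an imaged ROI, or a behavioural
session — is measured under each of three perfusion conditions (a control,
a receptor potentiator, a receptor antagonist). The package pairs each
analysis with a seeded generator that produces data with known ground truth,
so every estimator in the chain is verifiable by parameter recovery. This
vignette documents the generative models, the estimators, the tunable
parameters with their defaults, the numerical conventions, and the known
limitations.

## 1. Spike-train model and single-neuron metrics

### Generative model

A neuron's trial on `[-0.2, +0.3)` s around stimulus onset is the union of
two point processes:

* **Baseline**: homogeneous Poisson at `baseline_rate_hz` (default 2 Hz),
  identical across conditions. This encodes the experimental observation the
  package is built around: modulation acts on the evoked response, not on
  spontaneous firing.
* **Evoked** (amplitude `a > 0` only): rate
  `r(a) = gain_c * rmax * a^h / (a^h + a50^h) + offset_c`, a Hill
  input/output function (defaults `rmax = 120` Hz, `a50 = 50` um,
  `h = 1.5`, chosen to give a graded, saturating response function over the
  0–200 um stimulus set; the experiments show monotone saturating response
  functions but commit to no functional form, so the two-parameter Hill
  form is a documented stand-in). The per-condition gain is multiplicative
  on the evoked component only (defaults 1 / 2 / 0.78 for control /
  potentiated / antagonised, matching the regime the package models).

Evoked spike *counts* are generated by an equilibrium gamma-renewal process
with shape `kappa` (`renewal_shape`): inter-event intervals are
Gamma(`kappa`, rate `kappa * r`), burned in for ten mean intervals before
the window so the process is stationary. Stationarity gives
`E[count] = r * window` exactly and an asymptotic count Fano factor of
`1/kappa` (exactly Poisson at `kappa = 1`). The train is then *affinely
remapped* so that its first event falls at a drawn first-spike latency
(`latency_ms + jitter_ms * N(0,1)`, truncated into the window). The remap
preserves the event count exactly. This three-way construction is
deliberate: a literal "deterministic first spike plus renewal afterwards"
superposition adds a zero-variance spike to every trial and drags the
count Fano below `1/kappa` by a factor `(1 - 1/mean count)`, breaking the
calibration the dispersion parameter exists to provide. With the remap,
rate, dispersion, latency and jitter are independently controlled, which
is what the recovery tests require.

Per-neuron heterogeneity (`rmax` lognormal with CV `neuron_cv = 0.2`) is
drawn from a separate `param_seed`, so changing the data `seed` redraws
trials but never the ground truth.

### Metrics

* `evoked_rate()` counts spikes in the half-open window `[0, 0.05)` s
  (configurable) and reports count/window in spikes/s with SEM; a spike
  exactly at the window end is excluded. `response_scalars()` reduces this
  to baseline (amplitude-0 mean), maximum evoked response, and response
  range (max minus min of the per-amplitude means).
* `is_responsive()` compares per-trial counts in `[-0.1, 0)` vs `[0, 0.1)`
  with a paired t-test, per condition; a neuron is responsive if any
  condition is significant at alpha = 0.05. The significance clause is read
  per-window (not per-bin); only stimulus-present trials enter unless none
  exist.
* `first_spike_latency()` takes the first spike in `[0, 0.1)` per trial;
  the mean is over trials with at least one spike and the jitter is the
  sample SD (needing two such trials). Latency is conventionally reported
  at the highest amplitude for neurons passing the responsiveness gate.
* `fano_factor()` is sample variance (n−1 denominator; the convention is
  documented because "SD squared" does not pin it) over mean of the evoked
  window counts. Counts, not rates, are used — the rate-based value
  differs only by `1/window`.
* `fit_gain()` regresses modulated mean rates on control mean rates across
  the amplitude set by ordinary least squares. Slope > 1 with intercept
  near 0 reads as multiplicative gain; slope near 1 with positive
  intercept as additive; slope < 1 as suppression. Per-neuron
  classification uses two standard errors (`|slope − 1| > 2 SE` and
  `|intercept| > 2 SE`); the population-level reading
  (`population_gain_summary()`) uses the fraction of slopes above 1, the
  mean ± SEM, and a Wilcoxon signed-rank test of slopes against 1.

### A note on regression attenuation

Because the regressor in `fit_gain()` is itself a 30-trial mean, OLS is
subject to errors-in-variables attenuation: the expected slope is shrunk
by `SSX / (SSX + sum of sampling variances)` and the intercept is pushed
up by the complementary amount times the mean control rate. Under a
shallow graded tuning this bias is of order 1–3 Hz on the intercept. The
gain-recovery acceptance check therefore uses a steep, sparse tuning
(`a50 = 150`, `h = 5`, 100-ms window), for which the attenuation is
negligible and the check measures gain recovery rather than a property of
OLS. Analyses of real data inherit the same attenuation; interpreting
small intercepts from this regression requires the same care.

## 2. Fluorescence model and population metrics

### Generative model

Each ROI's true fractional fluorescence is

```
dff_i(t) = gain_c * tuning_i * hill(a) * K(t - onset)        (evoked)
         + sigma_spont * (lambda z(t) + sqrt(1 - lambda^2) e_i(t))  (spontaneous)
```

with `K` a peak-normalised double-exponential indicator kernel (rise 50 ms,
decay 500 ms — GCaMP7f-like), `z` a shared slow latent (AR(1), timescale
1 s) and `e_i` private white noise. Both `z` and `e_i` have unit variance,
so the spontaneous correlation of two ROIs is exactly
`lambda_i * lambda_j`; `loading_for_rho()` inverts this. The latent is
standardised to unit *empirical* variance within each session: a slow
latent has few effective degrees of freedom per recording, and its
realised variance would otherwise shift every pairwise correlation in the
session together, making the generator's ground truth hold only on
average across sessions rather than within each one.

Raw fluorescence is `F0_i * (1 + dff_i) + neuropil_scale * npil(t)` plus
white instrument noise. The recorded neuropil channel is `npil(t)` itself.
Instrument noise attenuates measured correlations below the latent value
by the usual variance ratio; the correlation-recovery check uses the pure
factor model (no instrument noise), where the latent value is exact.
A fraction `resp_fraction` (default 0.3) of ROIs carries an evoked
response; the rest are silent, emulating the sparse responsiveness of
layer 2/3 populations.

### Metrics

* `neuropil_correct()` subtracts the scalar session mean of the neuropil
  trace by default — the literal published procedure — with a frame-wise
  `r * npil(t)` option that also removes contamination dynamics.
* `compute_dff()` uses the session mean as `F0`, so each ROI's dF/F0 has
  session mean exactly 0 (asserted in tests); non-positive `F0` excludes
  the ROI with a warning.
* `evoked_dff()` takes, per trial, the mean dF/F0 over `[onset, onset+1 s)`
  minus the mean over the matched 1-s pre-window. Whether published evoked
  values are pre-window-subtracted is not stated in the source protocol;
  subtraction is the default here (it removes slow drift) and is
  configurable via `subtract_pre`.
* `classify_responsive_rois()` applies the same paired pre/post t-test as
  the ephys gate, at alpha = 0.05, and reports the responsive fraction per
  condition.
* `sort_population_heatmap()` orders ROIs by descending evoked response in
  a reference condition, ties broken by ROI id for determinism, and the
  same order is applied to the other conditions.

## 3. Noise correlations and the joint-PSTH

`spontaneous_segments()` removes `[onset − 0.5 s, onset + 3 s)` around
every stimulus (margins configurable; 3 s covers the response window plus
indicator decay) and keeps the remaining frames as separate segments.
`cross_correlogram()` mean-centres both signals and normalises lagged
cross-products by the geometric mean of the zero-lag autocorrelations, so
each autocorrelogram is 1 at lag 0 and the lag-0 cross value equals the
Pearson correlation coefficient. Negative correlations are retained (the
normalisation bounds magnitude by 1; clipping to `[0, 1]` would discard
sign information). Lagged products never span a segment splice.
Correlation strength is defined as the lag-0 value, not the global
maximum. The default maximum lag is 2 s at imaging frame rates.

`pairwise_matrix()` evaluates the strength for every unordered pair
(i < j); since lag-0 products cannot span a splice, it computes the
Pearson coefficient over the concatenated spontaneous frames directly,
and tests assert its equality with the correlogram path. The published
analysis this mirrors reports 36 pairs for 6 neurons (ordered or
self-inclusive pairs); the unordered convention (15 pairs for 6 neurons)
is used here and the discrepancy is noted, not resolved.

`jpsth()` builds the trial-averaged bin-by-bin coincidence matrix
`raw[b1, b2] = mean_t count_i(t, b1) * count_j(t, b2)`, a shift predictor
with neuron j's trials rotated by one (removing stimulus-locked structure)
and the corrected matrix `raw − predictor`, which isolates trial-by-trial
(noise) coupling.

## 4. Behavioural model and detection metrics

### Generative model

A session is `n_blocks = 48` blocks; each block is a seeded permutation of
the amplitude set (default 0/15/30/60/120 um — the figure-level set; the
protocol text elsewhere lists 20/40/80/120, and the set is configurable).
Inter-trial intervals are uniform on 5–10 s. The observer responds with
probability `guess + (1 − guess − lapse) * hill(a; threshold, slope)` on
stimulus trials and `guess` on catch trials; a response is a lick bout
(7 Hz, mean 4 licks) starting at an amplitude-dependent latency
`rt_factor_c * (0.25 + 0.35 * exp(−a / 40 um))` s, truncated into the 1-s
reward window. Default psychometric parameters per condition were chosen
once so that session-level d′ sits near 2.1 (control), 3.3 (potentiated)
and 2.1 (antagonised) with a condition-independent false-alarm probability
of 0.06 — the regime of the study the package models, in which detection
improves without any change in false alarms. The 400-ms, 40-Hz vibration
(15-ms deflections separated by 10-ms pauses) is available via
`deflection_train()`.

### Metrics

* `detect_licks()`: rising-edge threshold crossings with a 50-ms
  refractory period.
* `classify_trial()`: any lick in the 400 ms before onset invalidates the
  trial; otherwise a reward-window lick makes a stimulus trial a hit and a
  catch trial a false alarm; response time is the first reward-window lick.
* `lick_rate()` subtracts the pre-window lick rate from the reward-window
  lick rate in licks/s by default. The windows differ in length (0.4 vs
  1 s), so the published count subtraction mixes units; the per-second
  default is dimensionally consistent and `mode = "count"` reproduces the
  literal subtraction.
* `block_detection_rate()`: a block whose catch trial draws a
  reward-window lick is excluded (an engagement lapse); a catch trial
  invalidated by pre-stimulus licking also excludes the block, since it
  cannot be scored. Otherwise the rate is hits/4, always on the grid
  {0, 0.25, 0.5, 0.75, 1}.
* `d_prime()`: `qnorm(H) − qnorm(F)` with both rates truncated to
  `[0.01, 0.99]`, so d′ is finite and bounded by 4.65 in magnitude.
  Session d′ pools valid stimulus trials for H; F uses *all* valid catch
  trials, including those that excluded their block — block exclusion
  shapes the detection-rate curve only. d′ is computed per session and
  averaged across the five repeated sessions per condition, the design's
  unit of replication.

## 5. Statistical comparison layer

The three-condition within-subject design is compared nonparametrically:
`normality_gate()` (Kolmogorov–Smirnov against a normal with the sample's
moments; constant samples fail by convention) routes to
`friedman_dunn()` — Friedman omnibus on within-subject midranks with
Dunn's pairwise z-tests on mean ranks, Bonferroni-adjusted over the three
pairs (the "Dunn's multiple comparisons" of common graphing software;
the multiplicity family is per metric). `wilcoxon_signed_rank()` drops
zero differences, uses the exact distribution for n ≤ 25 without ties and
the tie-corrected normal approximation otherwise. `paired_t()` returns
p = 1 for identical samples (no evidence of difference, avoiding 0/0) and
p = 0 for a constant non-zero difference (the infinite-t limit).

For the design's own case — three conditions, up to 30 subjects, no ties —
the Friedman omnibus p comes from the *exact permutation null*, computed
by a dynamic programme over within-subject rank permutations and cached
per n. The chi-square approximation is visibly miscalibrated at these
sizes. A hard limit remains: at n = 23 the statistic takes only 139
distinct values and its largest null atom is 0.105, so *any* deterministic
p-value is a staircase at least 0.053 away from uniform in KS distance.
The exact p is conservative (P(p ≤ a) ≤ a at every level, asserted in
tests), which is the statistically sound resolution of that discreteness;
perfect uniformity is unattainable without randomised p-values.

## 6. Problem sizes, determinism and limitations

All randomness flows from one integer seed per generator through R's RNG;
identical seeds give bit-identical outputs, and ground truth depends only
on the configuration (including `param_seed`), never on the data seed.
The test suite runs desk-scale versions of every recovery: 10,000-trial
Fano calibrations, a 100-neuron gain-recovery cohort, 55 ROI pairs at
10,000 frames for correlation recovery, five 48-block sessions for d′
recovery, 10,000-replicate null calibrations for the statistical layer,
and a 100-run direction suite checking that every condition effect
(evoked response up, latency down, Fano down, pairwise correlation down,
detection rate and d′ up under potentiation; correlation up under
antagonism) points the right way in at least 95 runs. These sizes were
chosen as the smallest at which the Monte-Carlo error is well below each
tolerance.

What the generators do *not* emulate — and hence what passing tests do
not show about real data: biophysical spiking or indicator nonlinearity
and saturation; motion artefacts, ROI segmentation errors or slow drift
in imaging; stimulus-dependent (signal) correlation structure beyond the
shared gain; adaptation, learning or satiation within behavioural
sessions (real detection rates taper late in sessions; the simulated
observer is stationary); and any cell-type heterogeneity in the
modulation itself beyond lognormal response-scale variation.
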