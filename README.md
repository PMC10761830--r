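# sensorygain

Analysis and simulation of within-subject pharmacological experiments on
sensory cortex: how a neuromodulatory manipulation changes single-neuron
evoked responses, population synchrony and perceptual detection, measured
under three perfusion conditions (control aCSF, a receptor potentiator,
a receptor antagonist) in the same neurons, imaging fields and animals.

The package is aimed at systems neuroscientists analysing trial-organised
spike trains, two-photon calcium recordings and go/no-go lick behaviour.
Every analysis is paired with a seeded synthetic-data generator with known
ground truth, so the full chain is testable by parameter recovery without
any external recording.

## What it computes

**Single-neuron electrophysiology.** Evoked firing rates in a 50-ms
post-stimulus window, response-function scalars (baseline, maximum evoked
response, response range), first-spike latency and jitter in a 100-ms
window (gated on a paired pre/post t-test of responsiveness), and the
trial-to-trial variability as the Fano factor F = sigma^2 / mean of evoked
counts (1 for Poisson, below 1 for more reliable responses). Gain
decomposition regresses the modulated response function on the control one:

    r_mod(a) = slope * r_ctl(a) + intercept

slope > 1 with intercept ~ 0 is multiplicative gain; slope ~ 1 with
positive intercept is additive; slope < 1 is suppression.

**Population imaging.** Neuropil-corrected dF/F0 with the session mean as
F0, evoked responses in a 1-s window, responsive-ROI fractions, and
pairwise noise correlations: the lag-0 value of the normalised
cross-correlogram of ROI pairs over stimulus-free periods (equal to the
Pearson coefficient), plus a joint-PSTH with shift predictor to separate
stimulus-locked from trial-by-trial coupling.

**Detection behaviour.** Lick detection, trial classification (hit / miss /
false alarm / correct rejection / invalid), block-wise detection rates
(hits/4 per 5-trial block, blocks with catch-trial licks excluded), lick
rates, response times, and sensitivity

    d' = qnorm(H) - qnorm(F),  H, F truncated to [0.01, 0.99].

**Statistics.** Friedman test with Dunn's multiple comparisons across the
three conditions (exact permutation omnibus p for the tie-free
three-condition design up to n = 30), Wilcoxon signed-rank, paired t, and
a Kolmogorov–Smirnov normality gate.

**Simulators.** Gamma-renewal spike trains with independently controlled
rate (Hill tuning x condition gain), count dispersion (Fano ~ 1/kappa),
first-spike latency and jitter; a latent-factor fluorescence model with
exact pairwise spontaneous correlations; and a psychometric go/no-go
observer in a 48-block x 5-amplitude session design. All are deterministic
per seed and return their ground truth.

## Worked example

Simulate a 23-neuron three-condition cohort and a behavioural session set,
then run the headline analyses:

```r
library(sensorygain)

cfg <- ephys_sim_config(n_neurons = 23, seed = 42)
sim <- simulate_spike_trains(cfg)
rates <- evoked_rate(sim$raster, window_s = 0.05)
population_gain_summary(gain_table(rates, control = "aCSF"))
#>   condition     n fraction_slope_gt_1 mean_slope sem_slope p_slope_vs_1
#> 1 BQCA         23                   1      1.98     0.0227  0.000000238
#> 2 TD           23                   0      0.782    0.0143  0.000000238
```

Every neuron under the potentiator has slope > 1 (mean 1.98 ± 0.02,
recovering the planted gain of 2; signed-rank p vs 1 < 1e-6), and the
antagonist condition shows suppressive slopes (0.78). Latency and jitter
shrink under potentiation:

```r
first_spike_latency(sim$raster)   # per neuron x condition; cohort means:
#>   condition mean_latency_ms jitter_ms
#> 1      aCSF           14.91      3.58
#> 2      BQCA            9.94      2.04
#> 3        TD           17.47      4.54
```

A behavioural session set under the same three conditions:

```r
beh <- simulate_behavior_session(behavior_sim_config(seed = 42))
for (cn in names(beh$sessions)) {
  ss <- session_summary(beh$sessions[[cn]])
  cat(sprintf("%s: hit %.2f, FA %.3f, d-prime %.2f, detection %.2f\n",
              cn, ss$hit_rate, ss$fa_rate, ss$d_prime, ss$mean_detection_rate))
}
#> aCSF: hit 0.69, FA 0.125, d-prime 1.64, detection 0.70
#> BQCA: hit 0.95, FA 0.062, d-prime 3.16, detection 0.95
#> TD: hit 0.75, FA 0.042, d-prime 2.41, detection 0.76
```

Detection improves under the potentiator (d′ 3.16 vs 1.64) with no rise in
false alarms — the signature dissociation the design is built to detect.
`run_full_synthetic_study()` chains all three arms plus the statistics
layer into one seeded, reproducible report bundle, and
`inst/cli/sensorygain.R` exposes the simulate/analyze steps as shell
subcommands.

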