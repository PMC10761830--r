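#' Configuration for the spike-train simulator
#'
#' Defines a within-subject three-condition vibrotactile experiment: every
#' neuron is recorded under each condition (control perfusion, receptor
#' potentiation, receptor inhibition) at each stimulus amplitude, with a fixed
#' number of trials per amplitude. The evoked firing rate follows
#' `gain * rmax * hill(a) + offset` on top of an untouched baseline; evoked
#' counts are gamma-renewal distributed (count Fano factor approx. `1/kappa`),
#' and the first evoked spike is drawn at `latency_ms +/- jitter_ms`.
#'
#' Default condition parameters encode the study conditions this package
#' models: the potentiated condition doubles the evoked gain, shortens latency
#' and jitter and sharpens count dispersion (kappa 4); the antagonist condition
#' reduces gain below 1 and loosens timing. Baseline firing is identical across
#' conditions.
#'
#' @param amplitudes_um stimulus amplitudes in micrometres; must be sorted
#'   ascending and include 0 (the catch amplitude).
#' @param trials_per_amplitude trials per amplitude and condition.
#' @param baseline_rate_hz spontaneous firing rate, identical across conditions.
#' @param rmax_hz evoked rate at tuning saturation for a gain-1 condition.
#' @param a50_um,hill_exponent Hill tuning parameters (see [hill()]).
#' @param condition_gain named multiplicative factor on the evoked component.
#' @param condition_offset_hz named additive offset on the evoked rate (Hz).
#' @param latency_ms named mean first-spike latency per condition.
#' @param jitter_ms named across-trial s.d. of the first-spike latency.
#' @param renewal_shape named gamma-renewal shape kappa per condition
#'   (count Fano approx. 1/kappa; kappa = 1 is Poisson).
#' @param n_neurons number of neurons.
#' @param neuron_cv lognormal coefficient of variation of per-neuron `rmax_hz`.
#' @param pre_s,post_s trial window before/after stimulus onset (seconds).
#' @param evoked_window_s duration of the evoked spiking epoch (seconds).
#' @param seed integer seed driving all trial-level randomness.
#' @param param_seed seed for per-neuron parameter heterogeneity; kept separate
#'   so that changing `seed` redraws the data but never the ground truth.
#' @return an `ephys_sim_config` list, validated.
#' @export
ephys_sim_config <- function(amplitudes_um = c(0, 25, 50, 100, 200),
                             trials_per_amplitude = 30,
                             baseline_rate_hz = 2,
                             rmax_hz = 120,
                             a50_um = 50,
                             hill_exponent = 1.5,
                             condition_gain = c(aCSF = 1, BQCA = 2, TD = 0.78),
                             condition_offset_hz = c(aCSF = 0, BQCA = 0, TD = 0),
                             latency_ms = c(aCSF = 15, BQCA = 10, TD = 18),
                             jitter_ms = c(aCSF = 3, BQCA = 2, TD = 4),
                             renewal_shape = c(aCSF = 1, BQCA = 4, TD = 0.8),
                             n_neurons = 10,
                             neuron_cv = 0.2,
                             pre_s = 0.2,
                             post_s = 0.3,
                             evoked_window_s = 0.05,
                             seed = 1,
                             param_seed = 20240102) {
  conditions <- names(condition_gain)
  if (is.null(conditions) || any(conditions == "")) {
    stop("`condition_gain` must be a named vector of conditions", call. = FALSE)
  }
  if (is.unsorted(amplitudes_um, strictly = TRUE) || amplitudes_um[1] != 0) {
    stop("`amplitudes_um` must be strictly ascending and start at 0", call. = FALSE)
  }
  stopifnot(trials_per_amplitude >= 1, n_neurons >= 1,
            baseline_rate_hz >= 0, rmax_hz >= 0,
            pre_s >= 0.1, post_s >= 0.1, evoked_window_s > 0)
  condition_offset_hz <- assert_named_over(condition_offset_hz, conditions,
                                           "condition_offset_hz")
  latency_ms <- assert_named_over(latency_ms, conditions, "latency_ms")
  jitter_ms <- assert_named_over(jitter_ms, conditions, "jitter_ms")
  renewal_shape <- assert_named_over(renewal_shape, conditions, "renewal_shape")
  if (any(renewal_shape <= 0)) stop("renewal shape kappa must be > 0", call. = FALSE)
  if (any(jitter_ms < 0) || any(latency_ms < 0)) {
    stop("latencies and jitters must be non-negative", call. = FALSE)
  }
  # reject any condition x amplitude whose implied evoked rate is negative
  for (cn in conditions) {
    r <- condition_gain[[cn]] * rmax_hz * hill(amplitudes_um, a50_um, hill_exponent) +
      condition_offset_hz[[cn]] * (amplitudes_um > 0)
    if (any(r < 0)) {
      stop(sprintf("condition '%s' implies a negative evoked rate (gain %.3g, offset %.3g)",
                   cn, condition_gain[[cn]], condition_offset_hz[[cn]]), call. = FALSE)
    }
  }
  structure(list(
    amplitudes_um = amplitudes_um, trials_per_amplitude = trials_per_amplitude,
    baseline_rate_hz = baseline_rate_hz, rmax_hz = rmax_hz, a50_um = a50_um,
    hill_exponent = hill_exponent, conditions = conditions,
    condition_gain = condition_gain, condition_offset_hz = condition_offset_hz,
    latency_ms = latency_ms, jitter_ms = jitter_ms, renewal_shape = renewal_shape,
    n_neurons = n_neurons, neuron_cv = neuron_cv, pre_s = pre_s, post_s = post_s,
    evoked_window_s = evoked_window_s, seed = seed, param_seed = param_seed
  ), class = "ephys_sim_config")
}

# Per-neuron parameters, drawn from param_seed only.
ephys_neuron_params <- function(config) {
  with_seed_(config$param_seed, {
    tibble(
      neuron_id = seq_len(config$n_neurons),
      baseline_hz = config$baseline_rate_hz,
      rmax_hz = config$rmax_hz *
        exp(stats::rnorm(config$n_neurons, 0, config$neuron_cv)),
      a50_um = config$a50_um,
      hill_exponent = config$hill_exponent
    )
  })
}

#' True evoked rate implied by a simulator configuration
#'
#' Closed-form evoked-component rate `gain * rmax_i * hill(a) + offset` (Hz),
#' excluding baseline. Used by recovery tests as the ground-truth oracle.
#'
#' @param ground_truth the `ground_truth` element returned by
#'   [simulate_spike_trains()].
#' @param neuron_id,condition,amplitude_um scalars identifying the cell.
#' @return evoked rate in spikes/s.
#' @export
true_evoked_rate <- function(ground_truth, neuron_id, condition, amplitude_um) {
  np <- ground_truth$neurons[ground_truth$neurons$neuron_id == neuron_id, ]
  cp <- ground_truth$conditions[ground_truth$conditions$condition == condition, ]
  stopifnot(nrow(np) == 1, nrow(cp) == 1)
  if (amplitude_um == 0) return(0)
  cp$gain * np$rmax_hz * hill(amplitude_um, np$a50_um, np$hill_exponent) +
    cp$offset_hz
}

#' Simulate trial-organised spike trains under three-condition modulation
#'
#' For every neuron x condition x amplitude, generates `trials_per_amplitude`
#' trials on the window `[-pre_s, post_s)` (stimulus onset at 0). Baseline
#' spiking is a homogeneous Poisson process over the whole trial; the evoked
#' train on `[0, evoked_window_s)` is an equilibrium gamma-renewal process at
#' the condition's evoked rate, affinely remapped so that its first event
#' falls at the drawn first-spike latency. The remap preserves the event count
#' exactly, so the count Fano factor is the renewal value (about `1/kappa`)
#' while latency and jitter are controlled independently.
#'
#' @param config an [ephys_sim_config()].
#' @return a list with elements `raster` (tibble: `neuron_id`, `condition`,
#'   `amplitude_um`, `trial`, `spike_times_s` list-column, sorted within
#'   trial), `ground_truth` (per-neuron and per-condition true parameters,
#'   including the Fano target `1/kappa`) and `config`. Identical seeds give
#'   identical output.
#' @export
simulate_spike_trains <- function(config) {
  stopifnot(inherits(config, "ephys_sim_config"))
  neurons <- ephys_neuron_params(config)
  grid <- expand.grid(
    amplitude_um = config$amplitudes_um,
    condition = config$conditions,
    neuron_id = neurons$neuron_id,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  n_tr <- config$trials_per_amplitude
  rows <- with_seed_(config$seed, {
    lapply(seq_len(nrow(grid)), function(i) {
      nid <- grid$neuron_id[i]; cn <- grid$condition[i]; a <- grid$amplitude_um[i]
      np <- neurons[nid, ]
      r_e <- if (a > 0) {
        config$condition_gain[[cn]] * np$rmax_hz *
          hill(a, np$a50_um, np$hill_exponent) + config$condition_offset_hz[[cn]]
      } else 0
      spikes <- sim_trial_block(
        n_trials = n_tr, baseline_hz = np$baseline_hz, evoked_rate_hz = r_e,
        kappa = config$renewal_shape[[cn]],
        latency_s = config$latency_ms[[cn]] / 1000,
        jitter_s = config$jitter_ms[[cn]] / 1000,
        pre_s = config$pre_s, post_s = config$post_s,
        evoked_dur_s = config$evoked_window_s
      )
      tibble(neuron_id = nid, condition = cn, amplitude_um = a,
             trial = seq_len(n_tr), spike_times_s = spikes)
    })
  })
  raster <- dplyr::bind_rows(rows)
  ground_truth <- list(
    neurons = neurons,
    conditions = tibble(
      condition = config$conditions,
      gain = unname(config$condition_gain),
      offset_hz = unname(config$condition_offset_hz),
      latency_ms = unname(config$latency_ms),
      jitter_ms = unname(config$jitter_ms),
      renewal_shape = unname(config$renewal_shape),
      fano_target = 1 / unname(config$renewal_shape)
    )
  )
  list(raster = raster, ground_truth = ground_truth, config = config)
}

# One neuron x condition x amplitude block of trials.
sim_trial_block <- function(n_trials, baseline_hz, evoked_rate_hz, kappa,
                            latency_s, jitter_s, pre_s, post_s, evoked_dur_s) {
  span <- pre_s + post_s
  base_counts <- stats::rpois(n_trials, baseline_hz * span)
  base_times <- lapply(base_counts, function(k) {
    sort(stats::runif(k, -pre_s, post_s))
  })
  if (evoked_rate_hz > 0) {
    ev <- gamma_renewal_trials(evoked_rate_hz, kappa, evoked_dur_s, n_trials)
    t1 <- latency_s + jitter_s * stats::rnorm(n_trials)
    t1 <- pmin(pmax(t1, 0), 0.98 * evoked_dur_s)
    ev <- mapply(function(e, s) {
      n <- length(e)
      if (n == 0) return(e)
      if (n == 1) return(s)
      s + (e - e[1]) * (evoked_dur_s - s) / (evoked_dur_s - e[1])
    }, ev, t1, SIMPLIFY = FALSE)
  } else {
    ev <- rep(list(numeric(0)), n_trials)
  }
  mapply(function(b, e) sort(c(b, e)), base_times, ev, SIMPLIFY = FALSE)
}

#' Render spike times as a raw extracellular voltage trace
#'
#' Each spike is drawn as a stereotyped biphasic waveform (sharp negative
#' deflection followed by a slower positive rebound) added onto band-limited
#' Gaussian noise. Overlapping waveforms are summed. Supports validation of
#' threshold-based spike extraction against known ground truth.
#'
#' @param spike_times_s numeric vector of spike times (s) within
#'   `[0, duration_s)`.
#' @param duration_s trace duration (s).
#' @param sampling_rate_hz sampling rate; must be at least 20 kHz.
#' @param amplitude_uv peak-to-trough waveform amplitude (arbitrary units).
#' @param noise_sd noise standard deviation in the same units; 0 gives a
#'   noiseless trace.
#' @param noise_band_hz band of the noise (Hz), applied with a Butterworth
#'   filter; ignored when `noise_sd = 0`.
#' @return list with `trace` (numeric), `sample_rate_hz`, `times_s` (sample
#'   times) and `true_spike_times_s`.
#' @export
simulate_raw_voltage <- function(spike_times_s, duration_s,
                                 sampling_rate_hz = 30000,
                                 amplitude_uv = 100, noise_sd = 0,
                                 noise_band_hz = c(300, 6000)) {
  if (sampling_rate_hz < 20000) {
    stop("`sampling_rate_hz` must be at least 20 kHz", call. = FALSE)
  }
  n <- round(duration_s * sampling_rate_hz)
  trace <- numeric(n)
  # biphasic template, ~1.2 ms long, trough at t = 0.3 ms
  tw <- seq(0, 1.2e-3, by = 1 / sampling_rate_hz)
  wf <- -exp(-((tw - 3e-4) / 1e-4)^2) + 0.35 * exp(-((tw - 7e-4) / 2.5e-4)^2)
  wf <- amplitude_uv * wf / max(abs(wf))
  for (ts in spike_times_s) {
    i0 <- round(ts * sampling_rate_hz) + 1
    idx <- i0:(i0 + length(wf) - 1)
    keep <- idx >= 1 & idx <= n
    trace[idx[keep]] <- trace[idx[keep]] + wf[keep]
  }
  if (noise_sd > 0) {
    noise <- stats::rnorm(n, sd = noise_sd)
    nyq <- sampling_rate_hz / 2
    bf <- signal::butter(2, noise_band_hz / nyq, type = "pass")
    noise <- signal::filtfilt(bf, noise)
    noise <- noise * noise_sd / stats::sd(noise)
    trace <- trace + noise
  }
  list(trace = trace, sample_rate_hz = sampling_rate_hz,
       times_s = (seq_len(n) - 1) / sampling_rate_hz,
       true_spike_times_s = sort(spike_times_s))
}

#' Deflection train of a vibration stimulus
#'
#' Builds the onset times of the discrete deflections composing one vibration
#' stimulus: each deflection lasts `deflection_ms` and is followed by a
#' `pause_ms` pause, giving a repetition rate of
#' `1000 / (deflection_ms + pause_ms)` Hz (40 Hz for the defaults).
#'
#' @param duration_ms total stimulus duration (ms).
#' @param deflection_ms single deflection duration (ms).
#' @param pause_ms pause after each deflection (ms).
#' @return list with `onsets_ms`, `deflection_ms`, `pause_ms` and `rate_hz`.
#' @export
deflection_train <- function(duration_ms = 400, deflection_ms = 15, pause_ms = 10) {
  stopifnot(duration_ms > 0, deflection_ms > 0, pause_ms >= 0)
  period <- deflection_ms + pause_ms
  onsets <- seq(0, duration_ms - deflection_ms, by = period)
  list(onsets_ms = onsets, deflection_ms = deflection_ms, pause_ms = pause_ms,
       rate_hz = 1000 / period)
}
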