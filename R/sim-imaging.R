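#' Configuration for the population fluorescence simulator
#'
#' Generates per-condition two-photon-like recordings: each ROI's true
#' fractional fluorescence is the sum of (i) an evoked component — a
#' double-exponential indicator transient triggered at each stimulus onset and
#' scaled by the ROI's tuning, the amplitude's Hill factor and the condition
#' gain — and (ii) a spontaneous factor-model component
#' `sigma_spont * (loading * z(t) + sqrt(1 - loading^2) * eps_i(t))`, where
#' `z` is a shared slow latent (unit-variance AR(1)) and `eps_i` is private
#' white noise. With this normalisation the spontaneous pairwise correlation
#' between ROIs i and j is exactly `loading_i * loading_j`, so
#' [loading_for_rho()] gives the loading for any target correlation.
#' Raw fluorescence adds a per-ROI baseline `F0`, a shared neuropil
#' contamination `neuropil_scale * neuropil(t)` and optional white instrument
#' noise (which attenuates the measured correlation below the latent value).
#'
#' @param n_rois number of ROIs.
#' @param frame_rate_hz imaging frame rate (Hz).
#' @param trials_per_amplitude stimulus presentations per amplitude and
#'   condition.
#' @param amplitudes_um stimulus amplitudes (micrometres), ascending, incl. 0.
#' @param iti_s inter-trial interval between onsets (s).
#' @param lead_in_s stimulus-free recording at the start of each condition (s),
#'   guaranteeing spontaneous frames.
#' @param kernel_rise_s,kernel_decay_s indicator transient rise/decay times (s).
#' @param condition_gain named multiplicative gain on the evoked transient.
#' @param shared_latent_loading named per-condition loading in `[0, 1]`
#'   (scalar, applied to all ROIs) of the shared latent; the implied pairwise
#'   correlation is `loading^2`.
#' @param latent_tau_s timescale of the shared slow latent (s).
#' @param sigma_spont spontaneous fluctuation size in dF/F units.
#' @param resp_fraction fraction of ROIs carrying an evoked response.
#' @param evoked_peak_dff mean peak dF/F of a responsive ROI's transient at
#'   tuning saturation under gain 1.
#' @param a50_um,hill_exponent amplitude tuning (see [hill()]).
#' @param neuropil_scale contamination factor in `[0, 1]` applied to the
#'   shared neuropil trace.
#' @param noise_sd white instrument noise s.d. in raw fluorescence units.
#' @param seed integer seed for the data.
#' @param param_seed seed for per-ROI parameters (tuning, F0); separate so the
#'   ground truth is invariant to `seed`.
#' @return an `imaging_sim_config` list.
#' @export
imaging_sim_config <- function(n_rois = 20,
                               frame_rate_hz = 30,
                               trials_per_amplitude = 20,
                               amplitudes_um = c(0, 25, 50, 100, 250),
                               iti_s = 4,
                               lead_in_s = 60,
                               kernel_rise_s = 0.05,
                               kernel_decay_s = 0.5,
                               condition_gain = c(aCSF = 1, BQCA = 2, TD = 0.78),
                               shared_latent_loading = c(aCSF = sqrt(0.2),
                                                         BQCA = sqrt(0.1),
                                                         TD = sqrt(0.35)),
                               latent_tau_s = 1,
                               sigma_spont = 0.05,
                               resp_fraction = 0.3,
                               evoked_peak_dff = 0.4,
                               a50_um = 60,
                               hill_exponent = 1.5,
                               neuropil_scale = 0.3,
                               noise_sd = 2,
                               seed = 1,
                               param_seed = 20240102) {
  conditions <- names(condition_gain)
  if (is.null(conditions)) stop("`condition_gain` must be named", call. = FALSE)
  shared_latent_loading <- assert_named_over(shared_latent_loading, conditions,
                                             "shared_latent_loading")
  if (any(shared_latent_loading < 0 | shared_latent_loading > 1)) {
    stop("loadings must lie in [0, 1] (implied correlation loading^2 in [0, 1])",
         call. = FALSE)
  }
  if (is.unsorted(amplitudes_um, strictly = TRUE) || amplitudes_um[1] != 0) {
    stop("`amplitudes_um` must be strictly ascending and start at 0", call. = FALSE)
  }
  stopifnot(n_rois >= 2, frame_rate_hz > 0, trials_per_amplitude >= 1,
            kernel_rise_s > 0, kernel_decay_s > kernel_rise_s,
            neuropil_scale >= 0, neuropil_scale <= 1, noise_sd >= 0,
            sigma_spont > 0, iti_s > 1, lead_in_s >= 0)
  structure(list(
    n_rois = n_rois, frame_rate_hz = frame_rate_hz,
    trials_per_amplitude = trials_per_amplitude, amplitudes_um = amplitudes_um,
    iti_s = iti_s, lead_in_s = lead_in_s, kernel_rise_s = kernel_rise_s,
    kernel_decay_s = kernel_decay_s, conditions = conditions,
    condition_gain = condition_gain,
    shared_latent_loading = shared_latent_loading, latent_tau_s = latent_tau_s,
    sigma_spont = sigma_spont, resp_fraction = resp_fraction,
    evoked_peak_dff = evoked_peak_dff, a50_um = a50_um,
    hill_exponent = hill_exponent, neuropil_scale = neuropil_scale,
    noise_sd = noise_sd, seed = seed, param_seed = param_seed
  ), class = "imaging_sim_config")
}

#' Loading that yields a target pairwise spontaneous correlation
#'
#' In the unit-variance factor model of [imaging_sim_config()], two ROIs with
#' common loading `lambda` have spontaneous correlation `lambda^2`, hence
#' `lambda = sqrt(rho)`.
#'
#' @param rho target correlation in `[0, 1]`.
#' @return the loading.
#' @export
loading_for_rho <- function(rho) {
  stopifnot(rho >= 0, rho <= 1)
  sqrt(rho)
}

imaging_roi_params <- function(config) {
  with_seed_(config$param_seed, {
    responsive <- stats::runif(config$n_rois) < config$resp_fraction
    tibble(
      roi = seq_len(config$n_rois),
      responsive = responsive,
      tuning_peak_dff = ifelse(
        responsive,
        config$evoked_peak_dff * exp(stats::rnorm(config$n_rois, 0, 0.3)),
        0
      ),
      f0 = stats::runif(config$n_rois, 200, 600)
    )
  })
}

#' Simulate population fluorescence traces per condition
#'
#' @param config an [imaging_sim_config()].
#' @return list with `traces` (named list, one `roi_trace_set` per condition:
#'   fields `F` (ROI x frame raw fluorescence), `neuropil` (shared neuropil
#'   trace), `frame_times_s`, `onsets` tibble (`onset_s`, `amplitude_um`),
#'   `condition`, `roi_ids`), `ground_truth` (per-ROI tuning and F0, per-pair
#'   latent correlation, per-condition gain and loading) and `config`.
#' @export
simulate_population_traces <- function(config) {
  stopifnot(inherits(config, "imaging_sim_config"))
  rois <- imaging_roi_params(config)
  fr <- config$frame_rate_hz
  dt <- 1 / fr
  n_stim <- config$trials_per_amplitude * length(config$amplitudes_um)
  duration <- config$lead_in_s + n_stim * config$iti_s + 5
  n_frames <- round(duration * fr)
  frame_times <- (seq_len(n_frames) - 1) * dt
  # double-exponential indicator kernel, peak-normalised
  tk <- seq(0, config$kernel_decay_s * 6, by = dt)
  kern <- exp(-tk / config$kernel_decay_s) - exp(-tk / config$kernel_rise_s)
  kern <- kern / max(kern)

  traces <- with_seed_(config$seed, {
    out <- list()
    for (cn in config$conditions) {
      amps <- rep(config$amplitudes_um, times = config$trials_per_amplitude)
      amps <- sample(amps)
      onsets_s <- config$lead_in_s + (seq_along(amps) - 1) * config$iti_s
      lam <- config$shared_latent_loading[[cn]]
      z <- ar1_series(n_frames, config$latent_tau_s, dt)
      eps <- matrix(stats::rnorm(config$n_rois * n_frames),
                    nrow = config$n_rois)
      dff_true <- config$sigma_spont *
        (lam * matrix(z, nrow = config$n_rois, ncol = n_frames, byrow = TRUE) +
           sqrt(1 - lam^2) * eps)
      # evoked transients
      ev_profile <- numeric(n_frames)
      gain <- config$condition_gain[[cn]]
      stim_scale <- hill(amps, config$a50_um, config$hill_exponent)
      for (i in seq_along(amps)) {
        if (stim_scale[i] <= 0) next
        i0 <- round(onsets_s[i] * fr) + 1
        idx <- i0:(i0 + length(kern) - 1)
        keep <- idx <= n_frames
        ev_profile[idx[keep]] <- ev_profile[idx[keep]] + stim_scale[i] * kern[keep]
      }
      dff_true <- dff_true + gain * outer(rois$tuning_peak_dff, ev_profile)
      npil <- 100 * (1 + 0.2 * ar1_series(n_frames, 2, dt))
      f_raw <- rois$f0 * (1 + dff_true) +
        config$neuropil_scale *
          matrix(npil, nrow = config$n_rois, ncol = n_frames, byrow = TRUE)
      if (config$noise_sd > 0) {
        f_raw <- f_raw + matrix(stats::rnorm(length(f_raw), sd = config$noise_sd),
                                nrow = config$n_rois)
      }
      out[[cn]] <- structure(list(
        F = f_raw, neuropil = npil, frame_times_s = frame_times,
        onsets = tibble(onset_s = onsets_s, amplitude_um = amps),
        condition = cn, roi_ids = rois$roi,
        true_dff = dff_true
      ), class = "roi_trace_set")
    }
    out
  })

  loadings <- unname(config$shared_latent_loading)
  ground_truth <- list(
    rois = rois,
    conditions = tibble(
      condition = config$conditions,
      gain = unname(config$condition_gain),
      loading = loadings,
      pairwise_rho = loadings^2
    )
  )
  list(traces = traces, ground_truth = ground_truth, config = config)
}
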