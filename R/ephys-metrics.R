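#' Extract spike times from a raw voltage trace
#'
#' Band-pass filters the trace (Butterworth, zero-phase), estimates the noise
#' level robustly as `median(|x|) / 0.6745` and detects negative threshold
#' crossings at `threshold_sd` times that estimate. Each detection is placed
#' at the local extremum of the crossing, and a 1-ms refractory period is
#' enforced.
#'
#' @param trace numeric voltage trace.
#' @param sample_rate_hz sampling rate (Hz).
#' @param band_hz band-pass edges (Hz); must lie inside the Nyquist band.
#' @param threshold_sd detection threshold in robust noise s.d. units.
#' @param refractory_s minimum inter-spike interval (s).
#' @return numeric vector of spike times (s), possibly empty.
#' @export
extract_spikes <- function(trace, sample_rate_hz, band_hz = c(300, 6000),
                           threshold_sd = 5, refractory_s = 0.001) {
  nyq <- sample_rate_hz / 2
  if (band_hz[1] <= 0 || band_hz[2] >= nyq || band_hz[1] >= band_hz[2]) {
    stop("`band_hz` must satisfy 0 < low < high < Nyquist", call. = FALSE)
  }
  if (length(trace) < 10 * sample_rate_hz / band_hz[1]) {
    stop("trace shorter than the filter transient", call. = FALSE)
  }
  bf <- signal::butter(2, band_hz / nyq, type = "pass")
  x <- signal::filtfilt(bf, trace)
  noise_sd <- stats::median(abs(x)) / 0.6745
  if (noise_sd <= 1e-6 * max(abs(x))) {
    # noiseless trace: fall back to the scale of the signal itself so that
    # isolated waveforms are still detectable; a truly flat trace yields none
    noise_sd <- max(abs(x)) / (2 * threshold_sd)
    if (noise_sd == 0) return(numeric(0))
  }
  thr <- -threshold_sd * noise_sd
  below <- x < thr
  crossings <- which(below & !c(FALSE, below[-length(below)]))
  if (length(crossings) == 0) return(numeric(0))
  # place each event at the trough of its crossing epoch
  half <- round(0.0008 * sample_rate_hz)
  peaks <- vapply(crossings, function(i) {
    win <- i:min(i + half, length(x))
    win[which.min(x[win])]
  }, integer(1))
  times <- (peaks - 1) / sample_rate_hz
  keep <- c(TRUE, diff(times) > refractory_s)
  # iterate: after removing refractory violations, re-check gaps
  while (!all(keep)) {
    times <- times[keep]
    keep <- c(TRUE, diff(times) > refractory_s)
  }
  times
}

count_in_window <- function(spike_times_s, from, to) {
  vapply(spike_times_s, function(s) sum(s >= from & s < to), numeric(1))
}

#' Evoked firing-rate response functions
#'
#' Counts spikes in the half-open window `[0, window_s)` after stimulus onset
#' for every trial and reports the mean firing rate (count / window, spikes/s)
#' with its SEM per neuron x condition x amplitude. A spike exactly at the
#' window end is excluded.
#'
#' @param raster trial raster tibble (`neuron_id`, `condition`,
#'   `amplitude_um`, `trial`, `spike_times_s`).
#' @param window_s evoked count window (s), default 50 ms.
#' @return tibble with `neuron_id`, `condition`, `amplitude_um`,
#'   `mean_rate_hz`, `sem_rate_hz`, `n_trials`.
#' @export
evoked_rate <- function(raster, window_s = 0.05) {
  stopifnot(window_s > 0)
  raster |>
    dplyr::mutate(
      rate = count_in_window(.data$spike_times_s, 0, window_s) / window_s
    ) |>
    dplyr::group_by(.data$neuron_id, .data$condition, .data$amplitude_um) |>
    dplyr::summarise(
      mean_rate_hz = mean(.data$rate),
      sem_rate_hz = sem(.data$rate),
      n_trials = dplyr::n(),
      .groups = "drop"
    )
}

#' Scalar response-function parameters
#'
#' Reduces an [evoked_rate()] table to the three response-function scalars
#' per neuron x condition: baseline (the amplitude-0 mean rate), maximum
#' evoked response (largest per-amplitude mean) and response range (maximum
#' minus minimum of the per-amplitude means).
#'
#' @param rates output of [evoked_rate()].
#' @return tibble with `neuron_id`, `condition`, `baseline_hz`,
#'   `max_evoked_hz`, `response_range_hz`.
#' @export
response_scalars <- function(rates) {
  rates |>
    dplyr::group_by(.data$neuron_id, .data$condition) |>
    dplyr::summarise(
      baseline_hz = .data$mean_rate_hz[.data$amplitude_um == 0][1],
      max_evoked_hz = max(.data$mean_rate_hz),
      response_range_hz = max(.data$mean_rate_hz) - min(.data$mean_rate_hz),
      .groups = "drop"
    )
}

#' Whisker-responsiveness of recorded neurons
#'
#' Paired comparison of per-trial spike counts in a pre-stimulus window
#' `[-window_s, 0)` against the post-stimulus window `[0, window_s)`, per
#' neuron and condition; a neuron is responsive if the paired t-test is
#' significant in any condition. By default only stimulus-present trials
#' enter the comparison; if the raster contains no stimulus-present trials
#' all trials are used.
#'
#' @param raster trial raster tibble.
#' @param window_s comparison window length (s), default 100 ms.
#' @param alpha significance level.
#' @param stim_only use only amplitude > 0 trials when available.
#' @return tibble with `neuron_id`, `condition`, `p_value`, `n_trials` and
#'   the per-neuron flag `responsive` (p < alpha in any condition).
#' @export
is_responsive <- function(raster, window_s = 0.1, alpha = 0.05,
                          stim_only = TRUE) {
  use <- raster
  if (stim_only && any(raster$amplitude_um > 0)) {
    use <- raster[raster$amplitude_um > 0, ]
  }
  per_cond <- use |>
    dplyr::group_by(.data$neuron_id, .data$condition) |>
    dplyr::summarise(
      p_value = {
        pre <- count_in_window(.data$spike_times_s, -window_s, 0)
        post <- count_in_window(.data$spike_times_s, 0, window_s)
        paired_t(post, pre)$p_value
      },
      n_trials = dplyr::n(),
      .groups = "drop"
    )
  per_cond |>
    dplyr::group_by(.data$neuron_id) |>
    dplyr::mutate(responsive = any(.data$p_value < alpha)) |>
    dplyr::ungroup()
}

#' First-spike latency and jitter
#'
#' Per trial, the latency is the time of the first spike in the half-open
#' window `[0, window_s)`; trials without a spike are dropped. The mean is
#' reported over trials with at least one spike and the jitter is the sample
#' standard deviation (undefined below 2 such trials). By convention this is
#' reported at a single amplitude (the highest by default), for neurons that
#' pass the responsiveness gate of [is_responsive()].
#'
#' @param raster trial raster tibble.
#' @param amplitude_um amplitude at which to measure (default: highest).
#' @param window_s latency window (s), default 100 ms.
#' @return tibble per neuron x condition: `mean_latency_s`, `jitter_s`,
#'   `n_trials_with_spike`, `n_trials`, `defined` (at least one trial with a
#'   spike; jitter additionally needs two).
#' @export
first_spike_latency <- function(raster, amplitude_um = NULL, window_s = 0.1) {
  if (is.null(amplitude_um)) amplitude_um <- max(raster$amplitude_um)
  sub <- raster[raster$amplitude_um == amplitude_um, ]
  if (nrow(sub) == 0) stop("no trials at the requested amplitude", call. = FALSE)
  sub |>
    dplyr::group_by(.data$neuron_id, .data$condition) |>
    dplyr::summarise(
      lat = list(vapply(.data$spike_times_s, function(s) {
        s <- s[s >= 0 & s < window_s]
        if (length(s) == 0) NA_real_ else s[1]
      }, numeric(1))),
      n_trials = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      mean_latency_s = vapply(.data$lat, function(l) {
        l <- l[!is.na(l)]
        if (length(l) == 0) NA_real_ else mean(l)
      }, numeric(1)),
      jitter_s = vapply(.data$lat, function(l) {
        l <- l[!is.na(l)]
        if (length(l) < 2) NA_real_ else stats::sd(l)
      }, numeric(1)),
      n_trials_with_spike = vapply(.data$lat, function(l) sum(!is.na(l)),
                                   numeric(1)),
      defined = .data$n_trials_with_spike >= 1
    ) |>
    dplyr::select(-"lat")
}

#' Fano factor of trial counts
#'
#' Variance-to-mean ratio of spike counts across trials, using the sample
#' variance (n - 1 denominator). A value of 1 is the Poisson reference;
#' values below 1 indicate sub-Poisson (more reliable) responses.
#'
#' @param counts integer-valued counts, one per trial (length >= 2).
#' @return the Fano factor; `NA` with a warning when the mean count is 0.
#' @export
fano_factor <- function(counts) {
  stopifnot(length(counts) >= 2)
  m <- mean(counts)
  if (m == 0) {
    warning("mean count is 0; Fano factor undefined")
    return(NA_real_)
  }
  stats::var(counts) / m
}

#' Fano factors per neuron, condition and amplitude
#'
#' Applies [fano_factor()] to the evoked spike counts in `[0, window_s)`.
#' Counts (not rates) are used; the rate-based ratio differs only by the
#' constant factor `1 / window_s`.
#'
#' @param raster trial raster tibble.
#' @param window_s evoked count window (s), default 50 ms.
#' @return tibble with `neuron_id`, `condition`, `amplitude_um`,
#'   `mean_count`, `var_count`, `fano` (NA when the mean count is 0).
#' @export
fano_by_amplitude <- function(raster, window_s = 0.05) {
  raster |>
    dplyr::mutate(count = count_in_window(.data$spike_times_s, 0, window_s)) |>
    dplyr::group_by(.data$neuron_id, .data$condition, .data$amplitude_um) |>
    dplyr::summarise(
      mean_count = mean(.data$count),
      var_count = stats::var(.data$count),
      fano = ifelse(mean(.data$count) > 0,
                    stats::var(.data$count) / mean(.data$count), NA_real_),
      .groups = "drop"
    )
}

#' Gain decomposition of a modulated response function
#'
#' Ordinary least-squares line of the modulated mean rates against the
#' control mean rates across the common amplitude set. A slope above 1 with
#' an intercept near 0 indicates multiplicative gain modulation; a slope
#' near 1 with a positive intercept indicates an additive shift; a slope
#' below 1 indicates suppression. Per-fit classification uses
#' `|slope - 1| > 2 SE(slope)` and `|intercept| > 2 SE(intercept)`.
#'
#' @param control,modulated [evoked_rate()] tables (or any tibbles with
#'   `amplitude_um` and `mean_rate_hz`) for a single neuron each, over the
#'   same amplitude set with at least 3 amplitudes.
#' @return a `gain_fit` list: `slope`, `intercept`, `slope_se`,
#'   `intercept_se`, `sigma` (residual s.d.), `r_squared`, `n_amplitudes`,
#'   `classification` (multiplicative / additive / suppressive / mixed /
#'   none).
#' @export
fit_gain <- function(control, modulated) {
  ctl <- control[order(control$amplitude_um), ]
  mod <- modulated[order(modulated$amplitude_um), ]
  if (!identical(ctl$amplitude_um, mod$amplitude_um)) {
    stop("control and modulated response functions must share the amplitude set",
         call. = FALSE)
  }
  if (nrow(ctl) < 3) stop("gain fit needs at least 3 amplitudes", call. = FALSE)
  if (stats::var(ctl$mean_rate_hz) == 0) {
    stop("control rates have zero variance; slope undefined", call. = FALSE)
  }
  fit <- stats::lm(mod$mean_rate_hz ~ ctl$mean_rate_hz)
  # noiseless affine inputs are legitimate here; silence the perfect-fit note
  sm <- suppressWarnings(summary(fit))
  cf <- sm$coefficients
  slope <- cf[2, 1]; slope_se <- cf[2, 2]
  intercept <- cf[1, 1]; intercept_se <- cf[1, 2]
  mult <- slope - 1 > 2 * slope_se
  supp <- 1 - slope > 2 * slope_se
  addi <- abs(slope - 1) <= 2 * slope_se & intercept > 2 * intercept_se
  zero_int <- abs(intercept) <= 2 * intercept_se
  classification <- if (mult && zero_int) "multiplicative"
    else if (supp && zero_int) "suppressive"
    else if (addi) "additive"
    else if (mult || supp) "mixed"
    else "none"
  structure(list(
    slope = slope, intercept = intercept, slope_se = slope_se,
    intercept_se = intercept_se, sigma = sm$sigma,
    r_squared = sm$r.squared, n_amplitudes = nrow(ctl),
    classification = classification
  ), class = "gain_fit")
}

#' Gain fits for every neuron and modulated condition
#'
#' @param rates an [evoked_rate()] table covering all conditions.
#' @param control control condition label.
#' @return tibble, one row per neuron x non-control condition, with the
#'   [fit_gain()] fields.
#' @export
gain_table <- function(rates, control = "aCSF") {
  conds <- setdiff(unique(rates$condition), control)
  if (length(conds) == 0) stop("no modulated condition present", call. = FALSE)
  rows <- list()
  for (nid in unique(rates$neuron_id)) {
    ctl <- rates[rates$neuron_id == nid & rates$condition == control, ]
    for (cn in conds) {
      mod <- rates[rates$neuron_id == nid & rates$condition == cn, ]
      gf <- fit_gain(ctl, mod)
      rows[[length(rows) + 1]] <- tibble(
        neuron_id = nid, condition = cn, slope = gf$slope,
        intercept = gf$intercept, slope_se = gf$slope_se,
        intercept_se = gf$intercept_se, classification = gf$classification
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Population summary of gain fits
#'
#' Fraction of slopes above 1, mean +/- SEM of slopes and intercepts, and a
#' Wilcoxon signed-rank test of the slopes against 1 (and intercepts against
#' 0), per modulated condition.
#'
#' @param fits a [gain_table()] tibble (one condition or several).
#' @return tibble per condition: `n`, `fraction_slope_gt_1`, `mean_slope`,
#'   `sem_slope`, `p_slope_vs_1`, `mean_intercept`, `sem_intercept`,
#'   `p_intercept_vs_0`.
#' @export
population_gain_summary <- function(fits) {
  stopifnot(nrow(fits) >= 1)
  fits |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n = dplyr::n(),
      fraction_slope_gt_1 = mean(.data$slope > 1),
      mean_slope = mean(.data$slope),
      sem_slope = sem(.data$slope),
      p_slope_vs_1 = wilcoxon_signed_rank(.data$slope, mu = 1)$p_value,
      mean_intercept = mean(.data$intercept),
      sem_intercept = sem(.data$intercept),
      p_intercept_vs_0 = wilcoxon_signed_rank(.data$intercept, mu = 0)$p_value,
      .groups = "drop"
    )
}
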