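# Fixture builders shared across test files. Everything is generated in code;
# no data files.

# Minimal two-condition ephys config for fast simulations.
small_ephys_config <- function(seed = 1, n_neurons = 2,
                               trials_per_amplitude = 10, ...) {
  ephys_sim_config(
    n_neurons = n_neurons, trials_per_amplitude = trials_per_amplitude,
    condition_gain = c(aCSF = 1, BQCA = 2),
    condition_offset_hz = c(aCSF = 0, BQCA = 0),
    latency_ms = c(aCSF = 15, BQCA = 10),
    jitter_ms = c(aCSF = 3, BQCA = 2),
    renewal_shape = c(aCSF = 1, BQCA = 4),
    seed = seed, ...
  )
}

# Build a raster tibble directly from a list of spike-time vectors.
make_raster <- function(trials, neuron_id = 1L, condition = "aCSF",
                        amplitude_um = 200) {
  tibble::tibble(
    neuron_id = neuron_id, condition = condition,
    amplitude_um = amplitude_um, trial = seq_along(trials),
    spike_times_s = lapply(trials, sort)
  )
}

# Build one classified-ready behaviour block: licks are given relative to
# onset and shifted to absolute times.
make_block <- function(rel_licks, amplitudes = c(15, 30, 60, 120, 0),
                       block = 1L, condition = "aCSF", onset_step = 8) {
  stopifnot(length(rel_licks) == length(amplitudes))
  onsets <- seq(10, by = onset_step, length.out = length(amplitudes))
  tibble::tibble(
    trial = seq_along(amplitudes), block = block, condition = condition,
    amplitude_um = amplitudes, onset_s = onsets,
    lick_times_s = mapply(function(l, on) sort(l + on), rel_licks, onsets,
                          SIMPLIFY = FALSE)
  )
}

# Exact two-sided signed-rank p-value by enumerating all sign assignments.
exact_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  p_low <- mean(v_all <= v_obs)
  p_high <- mean(v_all >= v_obs)
  min(1, 2 * min(p_low, p_high))
}

# Exact Friedman omnibus p by enumerating within-subject rank permutations
# (small n and k only).
exact_friedman_p <- function(m) {
  n <- nrow(m); k <- ncol(m)
  stat_of <- function(r_mat) {
    cs <- colSums(r_mat)
    12 * sum((cs - n * (k + 1) / 2)^2) / (n * k * (k + 1))
  }
  obs <- stat_of(t(apply(m, 1, rank)))
  perms <- all_permutations(k)
  idx <- expand.grid(rep(list(seq_len(nrow(perms))), n))
  stats_all <- apply(idx, 1, function(row) {
    stat_of(do.call(rbind, lapply(row, function(i) perms[i, ])))
  })
  mean(stats_all >= obs - 1e-9)
}

# All permutations of 1..k (tiny k), no external dependency.
all_permutations <- function(k) {
  if (k == 1) return(matrix(1L))
  sub <- all_permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- setdiff(seq_len(k), i)
    cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }))
}
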