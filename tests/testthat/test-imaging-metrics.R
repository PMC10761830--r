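make_traces <- function(F, neuropil = rep(0, ncol(F)), frame_rate = 30,
                        onsets = tibble::tibble(onset_s = numeric(0),
                                                amplitude_um = numeric(0)),
                        condition = "aCSF") {
  structure(list(
    F = F, neuropil = neuropil,
    frame_times_s = (seq_len(ncol(F)) - 1) / frame_rate,
    onsets = onsets, condition = condition, roi_ids = seq_len(nrow(F))
  ), class = "roi_trace_set")
}

test_that("neuropil correction subtracts the scalar mean (framewise optional)", {
  F <- matrix(100, nrow = 2, ncol = 50)
  ts <- make_traces(F, neuropil = rep(20, 50))
  expect_equal(neuropil_correct(ts)$F, matrix(80, 2, 50))
  # zero neuropil is the identity
  ts0 <- make_traces(F)
  expect_equal(neuropil_correct(ts0)$F, F)
  # framewise mode removes time-varying contamination exactly
  npil <- 20 + sin(seq_len(50))
  tsv <- make_traces(sweep(F, 2, -0.7 * npil), neuropil = npil)
  expect_equal(neuropil_correct(tsv, method = "framewise", r = 0.7)$F,
               matrix(100, 2, 50))
})

test_that("frame-wise correction recovers the true signal better under contamination", {
  cfg <- imaging_sim_config(n_rois = 5, trials_per_amplitude = 3,
                            amplitudes_um = c(0, 100), iti_s = 3,
                            lead_in_s = 30,
                            condition_gain = c(aCSF = 1),
                            shared_latent_loading = c(aCSF = 0.3),
                            neuropil_scale = 0.3, noise_sd = 0, seed = 6)
  sim <- simulate_population_traces(cfg)
  ts <- sim$traces$aCSF
  cor_with_truth <- function(ts_corr) {
    d <- compute_dff(ts_corr)
    mean(vapply(seq_len(nrow(d$dff)), function(i) {
      stats::cor(d$dff[i, ], ts$true_dff[i, ])
    }, numeric(1)))
  }
  raw_cor <- cor_with_truth(ts)
  fw_cor <- cor_with_truth(neuropil_correct(ts, "framewise", r = 0.3))
  expect_gt(fw_cor, raw_cor)
})

test_that("dF/F0 uses the session-mean baseline, so its session mean is 0", {
  # constant trace -> all zeros
  d0 <- compute_dff(make_traces(matrix(100, 1, 60)))
  expect_equal(d0$dff, matrix(0, 1, 60))
  # mean-anchored step: +/- 0.5
  step <- c(rep(50, 30), rep(150, 30))
  d1 <- compute_dff(make_traces(matrix(step, 1, byrow = TRUE)))
  expect_equal(unique(round(d1$dff[1, ], 10)), c(-0.5, 0.5))
  # session-mean-zero invariant on arbitrary traces
  set.seed(8)
  F <- matrix(100 + stats::rnorm(5 * 300, sd = 10), nrow = 5)
  d2 <- compute_dff(make_traces(F))
  expect_true(all(abs(rowMeans(d2$dff)) < 1e-12))
  # non-positive F0 excludes the ROI with a warning
  bad <- rbind(rep(-5, 50), rep(100, 50))
  expect_warning(d3 <- compute_dff(make_traces(bad)), "non-positive F0")
  expect_equal(nrow(d3$dff), 1)
  expect_equal(d3$excluded_rois, 1)
})

test_that("evoked dF/F is zero on flat input, linear in scale, and null under shuffled onsets", {
  onsets <- tibble::tibble(onset_s = c(5, 15, 25), amplitude_um = c(100, 100, 100))
  flat <- compute_dff(make_traces(matrix(100, 2, 31 * 30), onsets = onsets))
  ev <- evoked_dff(flat)
  expect_true(all(ev$mean_evoked_dff == 0))
  # linearity: scaling dff scales evoked
  set.seed(3)
  F <- matrix(100 + stats::rnorm(2 * 31 * 30, sd = 5), nrow = 2)
  F[, 150:180] <- F[, 150:180] + 30  # transient after the 5-s onset
  d <- compute_dff(make_traces(F, onsets = onsets))
  ev1 <- evoked_dff(d)
  d_scaled <- d; d_scaled$dff <- 3 * d$dff
  ev3 <- evoked_dff(d_scaled)
  expect_equal(ev3$mean_evoked_dff, 3 * ev1$mean_evoked_dff, tolerance = 1e-12)
  # onset overrunning the recording is dropped with a warning
  onsets_bad <- tibble::tibble(onset_s = c(5, 30.8), amplitude_um = c(100, 100))
  d_bad <- compute_dff(make_traces(matrix(100, 1, 31 * 30), onsets = onsets_bad))
  expect_warning(ev_bad <- evoked_dff(d_bad), "dropped")
  expect_equal(unique(ev_bad$n_trials), 1)
})

test_that("evoked gain ratio of the simulated conditions is recovered", {
  cfg <- imaging_sim_config(n_rois = 12, trials_per_amplitude = 25,
                            amplitudes_um = c(0, 250), iti_s = 4,
                            lead_in_s = 20,
                            condition_gain = c(aCSF = 1, BQCA = 2),
                            shared_latent_loading = c(aCSF = 0.2, BQCA = 0.2),
                            resp_fraction = 1, neuropil_scale = 0,
                            noise_sd = 0, seed = 12)
  sim <- simulate_population_traces(cfg)
  evk <- lapply(sim$traces, function(ts) {
    ev <- evoked_dff(compute_dff(neuropil_correct(ts)))
    mean(ev$mean_evoked_dff[ev$amplitude_um == 250])
  })
  expect_lt(abs(evk$BQCA / evk$aCSF - 2), 0.25)
})

test_that("responsive-ROI classification recovers a planted responsive fraction", {
  cfg <- imaging_sim_config(n_rois = 40, trials_per_amplitude = 15,
                            amplitudes_um = c(0, 250), iti_s = 4,
                            lead_in_s = 20,
                            condition_gain = c(aCSF = 1),
                            shared_latent_loading = c(aCSF = 0.3),
                            resp_fraction = 0.5, evoked_peak_dff = 0.6,
                            neuropil_scale = 0, noise_sd = 0, seed = 14)
  sim <- simulate_population_traces(cfg)
  cls <- classify_responsive_rois(compute_dff(neuropil_correct(sim$traces$aCSF)))
  planted <- sim$ground_truth$rois$responsive
  frac <- attr(cls, "fraction_responsive")
  # within a binomial 99% band of the planted fraction
  p0 <- mean(planted)
  expect_lt(abs(frac - p0), 2.6 * sqrt(p0 * (1 - p0) / 40) + 0.05)
  # strong responders are individually detected
  strong <- sim$ground_truth$rois$tuning_peak_dff > 0.5
  expect_true(all(cls$responsive[strong]))
})

test_that("population heatmap ordering is a descending sort with deterministic ties", {
  ev <- tibble::tibble(roi = 1:4, condition = "aCSF", amplitude_um = 250,
                       mean_evoked_dff = c(0.1, 0.4, 0.4, 0.2),
                       sem_evoked_dff = 0, n_trials = 10)
  expect_equal(sort_population_heatmap(ev), c(2, 3, 4, 1))
  sorted <- ev; sorted$mean_evoked_dff <- c(4, 3, 2, 1)
  expect_equal(sort_population_heatmap(sorted), 1:4)
  rev_ev <- ev; rev_ev$mean_evoked_dff <- c(1, 2, 3, 4)
  expect_equal(sort_population_heatmap(rev_ev), 4:1)
  # oracle comparison on random input
  set.seed(5)
  rnd <- ev; rnd$mean_evoked_dff <- stats::rnorm(4)
  expect_equal(sort_population_heatmap(rnd),
               rnd$roi[order(rnd$mean_evoked_dff, decreasing = TRUE)])
})
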