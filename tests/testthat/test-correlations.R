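test_that("spontaneous segments exclude stimulus epochs and never merge across splices", {
  ft <- (0:999) / 10
  # no stimuli: one full segment
  segs <- spontaneous_segments(ft, numeric(0))
  expect_length(segs, 1)
  expect_equal(segs[[1]], 1:1000)
  # stimuli covering everything -> error
  expect_error(spontaneous_segments(ft, seq(0, 100, by = 2),
                                    pre_margin_s = 1, post_margin_s = 1.5),
               "no spontaneous frames")
  # two stimuli split the recording into three segments
  segs3 <- spontaneous_segments(ft, c(30, 60), pre_margin_s = 1,
                                post_margin_s = 3)
  expect_length(segs3, 3)
  expect_true(all(vapply(segs3, function(s) all(diff(s) == 1), logical(1))))
  excluded <- setdiff(1:1000, unlist(segs3))
  expect_true(all(ft[excluded] >= 29 & ft[excluded] < 63))
})

test_that("correlogram strength is the Pearson coefficient with its invariances", {
  set.seed(2)
  x <- stats::rnorm(500)
  y <- 0.5 * x + stats::rnorm(500)
  cc <- cross_correlogram(x, y, dt_s = 1 / 30)
  expect_equal(cc$strength, stats::cor(x, y), tolerance = 1e-12)
  # symmetry, self-correlation, boundedness
  expect_equal(cross_correlogram(y, x, dt_s = 1 / 30)$strength, cc$strength)
  auto <- cross_correlogram(x, x, dt_s = 1 / 30)
  expect_equal(auto$strength, 1)
  expect_true(all(abs(auto$values) <= 1 + 1e-12))
  expect_true(all(abs(cc$values) <= 1 + 1e-12))
  # zero-variance input is flagged with strength 0
  cz <- cross_correlogram(rep(1, 500), x, dt_s = 1 / 30)
  expect_true(cz$zero_variance)
  expect_equal(cz$strength, 0)
})

test_that("independent noise gives near-zero strength; a delay moves the peak off lag 0", {
  set.seed(7)
  n <- 10000
  a <- stats::rnorm(n); b <- stats::rnorm(n)
  cc <- cross_correlogram(a, b, dt_s = 1 / 30, max_lag_s = 0.5)
  expect_lt(abs(cc$strength), 0.02)
  # y = x delayed by k samples: peak at lag k * dt, lag-0 below the peak
  k <- 5
  y <- c(rep(0, k), a[seq_len(n - k)])
  cd <- cross_correlogram(a, y, dt_s = 1 / 30, max_lag_s = 0.5)
  expect_equal(cd$lags_s[which.max(cd$values)], k / 30)
  expect_lt(cd$strength, max(cd$values))
  # oracle: ccf at the same lag
  or <- stats::ccf(a, y, lag.max = 15, plot = FALSE)
  expect_equal(max(cd$values), max(or$acf), tolerance = 0.01)
})

test_that("correlations never span a splice boundary", {
  # two segments whose concatenation would look like a strong lag-1 signal
  set.seed(10)
  x <- stats::rnorm(300)
  y <- stats::rnorm(300)
  segs <- list(1:150, 151:300)
  cc <- cross_correlogram(x, y, dt_s = 1, max_lag_s = 3, segments = segs)
  # manual oracle at lag 1 computed within segments only
  mx <- mean(x); my <- mean(y)
  num <- sum((x[1:149] - mx) * (y[2:150] - my)) +
    sum((x[151:299] - mx) * (y[152:300] - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  expect_equal(cc$values[cc$lags_s == 1], num / den, tolerance = 1e-12)
})

test_that("pairwise matrix enumerates unordered pairs and recovers the factor-model rho", {
  cfg <- imaging_sim_config(n_rois = 6, trials_per_amplitude = 2,
                            amplitudes_um = c(0, 100), iti_s = 4,
                            lead_in_s = 300,
                            condition_gain = c(aCSF = 1),
                            shared_latent_loading = c(aCSF = loading_for_rho(0.3)),
                            neuropil_scale = 0, noise_sd = 0, seed = 4)
  sim <- simulate_population_traces(cfg)
  pm <- pairwise_matrix(compute_dff(neuropil_correct(sim$traces$aCSF)))
  expect_equal(pm$n_pairs, choose(6, 2))
  expect_true(all(pm$pairs$i < pm$pairs$j))
  expect_lt(abs(pm$mean_strength - 0.3), 0.05)
  # strength equals the correlogram value for the same pair
  d <- compute_dff(neuropil_correct(sim$traces$aCSF))
  segs <- spontaneous_segments(d$frame_times_s, d$onsets$onset_s)
  cc <- cross_correlogram(d$dff[1, ], d$dff[2, ], dt_s = 1 / 30,
                          segments = segs)
  expect_equal(pm$pairs$strength[pm$pairs$i == 1 & pm$pairs$j == 2],
               cc$strength, tolerance = 1e-10)
})

test_that("estimated strength converges to the true rho with sample size", {
  errs <- vapply(c(40, 150, 600), function(lead) {
    cfg <- imaging_sim_config(n_rois = 8, trials_per_amplitude = 1,
                              amplitudes_um = c(0, 100), iti_s = 4,
                              lead_in_s = lead,
                              condition_gain = c(aCSF = 1),
                              shared_latent_loading = c(aCSF = loading_for_rho(0.25)),
                              neuropil_scale = 0, noise_sd = 0, seed = 44)
    sim <- simulate_population_traces(cfg)
    pm <- pairwise_matrix(compute_dff(neuropil_correct(sim$traces$aCSF)))
    abs(pm$mean_strength - 0.25)
  }, numeric(1))
  expect_lt(errs[3], 0.03)
  expect_lt(errs[3], errs[1])
})

test_that("raising the shared loading raises the mean pairwise strength", {
  strengths <- vapply(c(0.1, 0.3, 0.5), function(rho) {
    cfg <- imaging_sim_config(n_rois = 8, trials_per_amplitude = 1,
                              amplitudes_um = c(0, 100), iti_s = 4,
                              lead_in_s = 150,
                              condition_gain = c(aCSF = 1),
                              shared_latent_loading = c(aCSF = loading_for_rho(rho)),
                              neuropil_scale = 0, noise_sd = 0, seed = 9)
    sim <- simulate_population_traces(cfg)
    pairwise_matrix(compute_dff(neuropil_correct(sim$traces$aCSF)))$mean_strength
  }, numeric(1))
  expect_true(all(diff(strengths) > 0))
})

test_that("jPSTH shift predictor removes rate structure and keeps noise coupling", {
  set.seed(6)
  n_tr <- 200
  # independent Poisson trains: corrected ~ 0 elementwise
  pois <- function() lapply(seq_len(n_tr), function(i) {
    sort(stats::runif(stats::rpois(1, 5), 0, 0.1))
  })
  jp <- jpsth(pois(), pois(), bin_s = 0.02, window_s = c(0, 0.1))
  expect_true(all(jp$raw >= 0))
  expect_true(all(jp$predictor >= 0))
  expect_equal(jp$corrected, jp$raw - jp$predictor)
  expect_lt(max(abs(jp$corrected)), 0.5)
  expect_lt(mean(abs(jp$corrected)), 0.15)
  # identical trains: strong positive diagonal
  tr <- pois()
  jp2 <- jpsth(tr, tr, bin_s = 0.02, window_s = c(0, 0.1))
  expect_gt(mean(diag(jp2$corrected)), 0.5)
  expect_gt(mean(diag(jp2$corrected)), mean(jp2$corrected[upper.tri(jp2$corrected)]))
  # planted zero-lag coincidences scale the diagonal mass
  plant <- function(p_coinc, seed) {
    set.seed(seed)
    base_i <- pois(); base_j <- pois()
    for (t in seq_len(n_tr)) {
      if (stats::runif(1) < p_coinc) {
        s <- stats::runif(1, 0, 0.1)
        base_i[[t]] <- sort(c(base_i[[t]], s))
        base_j[[t]] <- sort(c(base_j[[t]], s))
      }
    }
    sum(diag(jpsth(base_i, base_j, bin_s = 0.02,
                   window_s = c(0, 0.1))$corrected))
  }
  expect_gt(plant(0.9, 2), plant(0.2, 2))
  expect_error(jpsth(list(1:2), list(1:2, 3)), "match")
})
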