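test_that("lick detection finds rising edges with a refractory period", {
  sr <- 1000
  flat <- rep(0, 2000)
  expect_length(detect_licks(flat, sr, threshold = 0.5), 0)
  # two square pulses 1 s apart
  v <- rep(0, 2500)
  v[501:520] <- 1; v[1501:1520] <- 1
  expect_equal(detect_licks(v, sr, 0.5), c(0.5, 1.5))
  # simulated 7-Hz bout: inter-lick intervals ~143 ms
  bout_times <- seq(0.2, by = 1 / 7, length.out = 8)
  v2 <- rep(0, 2000)
  for (t in bout_times) v2[round(t * sr) + (1:10)] <- 1
  est <- detect_licks(v2, sr, 0.5)
  expect_length(est, 8)
  expect_equal(mean(diff(est)), 1 / 7, tolerance = 0.01)
})

test_that("lick rate subtracts per-second pre rate from post rate", {
  expect_equal(lick_rate(numeric(0), onset_s = 10), 0)
  expect_equal(lick_rate(10 + c(0.1, 0.5, 0.9), 10), 3)
  expect_equal(lick_rate(10 - 0.2, 10), -1 / 0.4)
  # count mode subtracts raw counts
  expect_equal(lick_rate(10 + c(0.1, -0.2), 10, mode = "count"), 0)
})

test_that("trial classification follows the hit/FA/invalid rules", {
  hit <- classify_trial(60, 10, 10 + 0.3)
  expect_equal(hit$outcome, "hit")
  expect_equal(hit$response_time_s, 0.3)
  fa <- classify_trial(0, 10, 10 + 0.5)
  expect_equal(fa$outcome, "false_alarm")
  expect_equal(fa$response_time_s, 0.5)
  expect_equal(classify_trial(120, 10, 10 - 0.2)$outcome, "invalid")
  expect_equal(classify_trial(30, 10, numeric(0))$outcome, "miss")
  expect_equal(classify_trial(0, 10, numeric(0))$outcome, "correct_rejection")
  # lick after the reward window is not a response
  expect_equal(classify_trial(30, 10, 10 + 1.2)$outcome, "miss")
})

test_that("block scoring gives hits/4 and excludes blocks with catch-trial licks", {
  hit_all <- list(0.3, 0.25, 0.2, 0.15, numeric(0))
  b <- classify_trials(make_block(hit_all))
  out <- block_detection_rate(b)
  expect_false(out$excluded)
  expect_equal(out$detection_rate, 1)
  # two hits, clean catch: 0.5
  two <- list(0.3, 0.25, numeric(0), numeric(0), numeric(0))
  out2 <- block_detection_rate(classify_trials(make_block(two)))
  expect_equal(out2$detection_rate, 0.5)
  # any catch-trial lick excludes the block
  fa_block <- list(0.3, 0.25, 0.2, 0.15, 0.4)
  out3 <- block_detection_rate(classify_trials(make_block(fa_block)))
  expect_true(out3$excluded)
  expect_equal(out3$exclusion_reason, "catch_false_alarm")
  expect_true(is.na(out3$detection_rate))
  # detection rate always lies on the {0, .25, .5, .75, 1} grid
  set.seed(3)
  for (i in 1:20) {
    licks <- lapply(1:5, function(j) {
      if (stats::runif(1) < 0.5) stats::runif(1, 0, 0.9) else numeric(0)
    })
    r <- block_detection_rate(classify_trials(make_block(licks)))
    if (!r$excluded) expect_true(r$detection_rate %in% c(0, 0.25, 0.5, 0.75, 1))
  }
  # incomplete block is excluded with a warning
  expect_warning(inc <- block_detection_rate(
    classify_trials(make_block(list(0.3, numeric(0)), amplitudes = c(15, 0)))
  ), "incomplete")
  expect_true(inc$excluded)
})

test_that("d-prime matches the quantile-function oracle and its monotonicity", {
  expect_equal(d_prime(0.5, 0.5), 0)
  expect_equal(d_prime(1, 0), stats::qnorm(0.99) - stats::qnorm(0.01))
  expect_equal(d_prime(0.9, 0.1), 2 * stats::qnorm(0.9))
  # strictly increasing in H, decreasing in F; d'(H, H) = 0; bounded
  hs <- seq(0.02, 0.98, by = 0.08)
  expect_true(all(diff(d_prime(hs, 0.1)) > 0))
  expect_true(all(diff(d_prime(0.9, hs)) < 0))
  expect_true(all(d_prime(hs, hs) == 0))
  cap <- stats::qnorm(0.99) - stats::qnorm(0.01)
  expect_true(all(abs(d_prime(c(0, 1, 0.5), c(1, 0, 0.5))) <= cap))
})

test_that("session structure: blocks are complete permutations with uniform ITIs", {
  cfg <- behavior_sim_config(n_blocks = 12, seed = 5)
  sim <- simulate_behavior_session(cfg)
  for (cn in names(sim$sessions)) {
    s <- sim$sessions[[cn]]
    expect_equal(nrow(s), 12 * 5)
    per_block <- split(s$amplitude_um, s$block)
    for (b in per_block) expect_setequal(b, cfg$amplitudes_um)
    gaps <- diff(s$onset_s)
    expect_true(all(gaps >= cfg$iti_range_s[1] - 1e-9 &
                      gaps <= cfg$iti_range_s[2] + 1e-9))
  }
  # determinism
  sim2 <- simulate_behavior_session(cfg)
  expect_identical(sim$sessions, sim2$sessions)
})

test_that("degenerate observers behave as constructed", {
  # perfect observer: threshold far below the lowest amplitude, no lapse/guess
  perfect <- behavior_sim_config(
    threshold_um = c(x = 0.5), slope = c(x = 3),
    lapse = c(x = 0), guess = c(x = 0), n_blocks = 10, seed = 2
  )
  s <- classify_trials(simulate_behavior_session(perfect)$sessions$x)
  expect_true(all(s$outcome[s$amplitude_um > 0] == "hit"))
  expect_true(all(s$outcome[s$amplitude_um == 0] == "correct_rejection"))
  ss <- session_summary(simulate_behavior_session(perfect)$sessions$x)
  expect_equal(ss$hit_rate, 1)
  expect_equal(ss$fa_rate, 0)
  expect_equal(ss$d_prime, stats::qnorm(0.99) - stats::qnorm(0.01))
  # guess = 1: every catch trial licked, every block excluded
  guesser <- behavior_sim_config(
    threshold_um = c(x = 0.5), slope = c(x = 3),
    lapse = c(x = 0), guess = c(x = 1), n_blocks = 10, seed = 3
  )
  ss2 <- session_summary(simulate_behavior_session(guesser)$sessions$x)
  expect_equal(ss2$n_blocks_excluded, 10)
  expect_equal(ss2$fa_rate, 1)
})

test_that("session summary aggregates rates, RTs and the FA-before/after-exclusion ordering", {
  cfg <- behavior_sim_config(seed = 21)
  sim <- simulate_behavior_session(cfg, conditions = "aCSF")
  s <- sim$sessions$aCSF
  ss <- session_summary(s)
  expect_equal(sum(ss$by_amplitude$n_trials), 240)
  expect_true(ss$fa_rate >= 0 && ss$fa_rate <= 1)
  expect_true(is.finite(ss$d_prime))
  # RT decreases with amplitude by construction (direction check)
  rts <- ss$by_amplitude$mean_response_time_s[ss$by_amplitude$amplitude_um > 0]
  expect_lt(rts[length(rts)], rts[1])
  # FA over all catch trials >= FA over retained (non-excluded) blocks only
  cls <- classify_trials(s)
  blocks <- ss$blocks
  kept <- blocks$block[!blocks$excluded]
  catch <- cls[cls$amplitude_um == 0 & cls$outcome != "invalid", ]
  fa_all <- mean(catch$outcome == "false_alarm")
  fa_kept <- mean(catch$outcome[catch$block %in% kept] == "false_alarm")
  expect_gte(fa_all, fa_kept)
})
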