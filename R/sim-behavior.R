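#' Configuration for the go/no-go detection-session simulator
#'
#' Simulates a head-fixed whisker-vibration detection session: stimuli are
#' delivered in pseudorandom blocks, each block containing every amplitude
#' exactly once (one of them the 0-um catch trial). The observer responds
#' according to a psychometric function
#' `p(a) = guess + (1 - guess - lapse) * hill(a)` for stimulus-present trials
#' and licks on catch trials with probability `guess` (the false-alarm
#' probability). On a response, a lick bout starts at an amplitude-dependent
#' latency inside the reward window.
#'
#' Default psychometric parameters encode the study conditions: a control
#' observer with session d-prime near 2.1, a potentiated condition with
#' steeper sensitivity (d-prime near 3.3) and an antagonist condition back
#' near control, with an identical false-alarm probability across conditions.
#'
#' @param amplitudes_um amplitudes per block (ascending, including the 0-um
#'   catch trial).
#' @param n_blocks blocks per session.
#' @param threshold_um,slope,lapse,guess named per-condition psychometric
#'   parameters; `guess` is the false-alarm probability, `lapse` caps the
#'   asymptotic hit rate at `1 - lapse`.
#' @param rt_floor_s,rt_range_s,rt_tau_um mean first-lick latency model:
#'   `rt_floor_s + rt_range_s * exp(-a / rt_tau_um)` seconds at amplitude `a`.
#' @param rt_factor named per-condition multiplicative factor on the mean
#'   response latency (faster responding under potentiation).
#' @param rt_sd_s trial-to-trial s.d. of the first-lick latency.
#' @param lick_rate_hz within-bout lick rate.
#' @param bout_licks mean number of licks per bout.
#' @param spont_lick_rate_hz rate of task-unrelated licks (default 0); these
#'   can land in the pre-stimulus window and invalidate trials.
#' @param iti_range_s inter-trial interval range (uniform), seconds.
#' @param stimulus_duration_s vibration duration (s).
#' @param reward_window_s response window after onset (s).
#' @param pre_window_s no-lick window before onset defining a valid trial (s).
#' @param seed integer seed.
#' @return a `behavior_sim_config` list.
#' @export
behavior_sim_config <- function(amplitudes_um = c(0, 15, 30, 60, 120),
                                n_blocks = 48,
                                threshold_um = c(aCSF = 20, BQCA = 5, TD = 19),
                                slope = c(aCSF = 1.6, BQCA = 1.8, TD = 1.6),
                                lapse = c(aCSF = 0.05, BQCA = 0.01, TD = 0.04),
                                guess = c(aCSF = 0.06, BQCA = 0.06, TD = 0.06),
                                rt_floor_s = 0.25,
                                rt_range_s = 0.35,
                                rt_tau_um = 40,
                                rt_factor = c(aCSF = 1, BQCA = 0.85, TD = 1.15),
                                rt_sd_s = 0.08,
                                lick_rate_hz = 7,
                                bout_licks = 4,
                                spont_lick_rate_hz = 0,
                                iti_range_s = c(5, 10),
                                stimulus_duration_s = 0.4,
                                reward_window_s = 1,
                                pre_window_s = 0.4,
                                seed = 1) {
  conditions <- names(threshold_um)
  if (is.null(conditions)) stop("`threshold_um` must be named", call. = FALSE)
  # unsupplied per-condition defaults recycle a neutral value when the
  # condition set does not match the default three-condition design
  cond_param <- function(x, supplied, neutral, what) {
    if (all(conditions %in% names(x))) return(x[conditions])
    if (supplied) {
      stop(sprintf("`%s` must be named for every condition (%s)",
                   what, paste(conditions, collapse = ", ")), call. = FALSE)
    }
    stats::setNames(rep(neutral, length(conditions)), conditions)
  }
  slope <- cond_param(slope, !missing(slope), 1.6, "slope")
  lapse <- cond_param(lapse, !missing(lapse), 0.05, "lapse")
  guess <- cond_param(guess, !missing(guess), 0.06, "guess")
  rt_factor <- cond_param(rt_factor, !missing(rt_factor), 1, "rt_factor")
  if (is.unsorted(amplitudes_um, strictly = TRUE) || amplitudes_um[1] != 0) {
    stop("`amplitudes_um` must be strictly ascending and start at 0", call. = FALSE)
  }
  p_top <- guess + (1 - guess - lapse)
  if (any(guess < 0 | guess > 1) || any(lapse < 0) || any(p_top > 1)) {
    stop("psychometric probabilities must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(n_blocks >= 1, length(iti_range_s) == 2, iti_range_s[1] > 0,
            iti_range_s[2] >= iti_range_s[1], reward_window_s > 0,
            pre_window_s > 0, spont_lick_rate_hz >= 0)
  structure(list(
    amplitudes_um = amplitudes_um, n_blocks = n_blocks, conditions = conditions,
    threshold_um = threshold_um, slope = slope, lapse = lapse, guess = guess,
    rt_floor_s = rt_floor_s, rt_range_s = rt_range_s, rt_tau_um = rt_tau_um,
    rt_factor = rt_factor, rt_sd_s = rt_sd_s, lick_rate_hz = lick_rate_hz,
    bout_licks = bout_licks, spont_lick_rate_hz = spont_lick_rate_hz,
    iti_range_s = iti_range_s, stimulus_duration_s = stimulus_duration_s,
    reward_window_s = reward_window_s, pre_window_s = pre_window_s, seed = seed
  ), class = "behavior_sim_config")
}

#' True response probability of the simulated observer
#'
#' @param config a [behavior_sim_config()].
#' @param condition condition label.
#' @param amplitude_um amplitudes (0 gives the false-alarm probability).
#' @return probability of at least one reward-window lick.
#' @export
true_response_prob <- function(config, condition, amplitude_um) {
  g <- config$guess[[condition]]
  l <- config$lapse[[condition]]
  th <- config$threshold_um[[condition]]
  s <- config$slope[[condition]]
  ifelse(amplitude_um > 0,
         g + (1 - g - l) * hill(amplitude_um, th, s),
         g)
}

#' Simulate one go/no-go detection session per condition
#'
#' Each session has `n_blocks` blocks; within a block the amplitude order is
#' a seeded permutation. Inter-trial intervals are uniform on `iti_range_s`.
#'
#' @param config a [behavior_sim_config()].
#' @param conditions conditions to simulate (default: all in the config).
#' @return list with `sessions` (named list of tibbles, one per condition:
#'   columns `trial`, `block`, `condition`, `amplitude_um`, `onset_s`,
#'   `lick_times_s` list-column of absolute lick times) and `ground_truth`
#'   (per-condition hit/FA probabilities per amplitude and the implied
#'   truncated d-prime), and `config`.
#' @export
simulate_behavior_session <- function(config, conditions = config$conditions) {
  stopifnot(inherits(config, "behavior_sim_config"))
  stim_amps <- config$amplitudes_um[config$amplitudes_um > 0]
  sessions <- with_seed_(config$seed, {
    out <- list()
    for (cn in conditions) {
      amps <- unlist(lapply(seq_len(config$n_blocks),
                            function(b) sample(config$amplitudes_um)))
      n_trials <- length(amps)
      itis <- stats::runif(n_trials, config$iti_range_s[1], config$iti_range_s[2])
      onsets <- cumsum(itis)
      licks <- vector("list", n_trials)
      for (i in seq_len(n_trials)) {
        p <- true_response_prob(config, cn, amps[i])
        tr_licks <- numeric(0)
        if (stats::runif(1) < p) {
          mu_rt <- config$rt_factor[[cn]] *
            (config$rt_floor_s +
               config$rt_range_s * exp(-max(amps[i], 1) / config$rt_tau_um))
          rt <- stats::rnorm(1, mu_rt, config$rt_sd_s)
          rt <- min(max(rt, 0.05), config$reward_window_s - 0.02)
          n_licks <- max(1, stats::rpois(1, config$bout_licks))
          gaps <- stats::rexp(n_licks - 1, config$lick_rate_hz) + 1 / (2 * config$lick_rate_hz)
          tr_licks <- rt + c(0, cumsum(gaps))
        }
        if (config$spont_lick_rate_hz > 0) {
          span <- c(-config$pre_window_s - 1, config$reward_window_s + 1)
          k <- stats::rpois(1, config$spont_lick_rate_hz * diff(span))
          tr_licks <- c(tr_licks, stats::runif(k, span[1], span[2]))
        }
        licks[[i]] <- sort(onsets[i] + tr_licks)
      }
      out[[cn]] <- tibble(
        trial = seq_len(n_trials),
        block = rep(seq_len(config$n_blocks), each = length(config$amplitudes_um)),
        condition = cn,
        amplitude_um = amps,
        onset_s = onsets,
        lick_times_s = licks
      )
    }
    out
  })
  gt_rows <- lapply(conditions, function(cn) {
    p_hit <- true_response_prob(config, cn, stim_amps)
    fa <- config$guess[[cn]]
    tibble(condition = cn,
           amplitude_um = list(stim_amps),
           hit_prob = list(p_hit),
           fa_prob = fa,
           mean_hit_prob = mean(p_hit),
           d_prime = d_prime(mean(p_hit), fa))
  })
  list(sessions = sessions, ground_truth = dplyr::bind_rows(gt_rows),
       config = config)
}
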