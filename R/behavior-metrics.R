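#' Detect licks from a capacitive sensor voltage
#'
#' Rising-edge threshold crossings with a refractory period: a lick is
#' registered whenever the voltage crosses the threshold from below, and
#' further crossings within `refractory_s` are ignored.
#'
#' @param voltage numeric capacitive voltage trace.
#' @param sample_rate_hz sampling rate (Hz).
#' @param threshold detection threshold (same units as `voltage`); must
#'   exceed the baseline noise.
#' @param refractory_s minimum inter-lick interval (s), default 50 ms.
#' @return numeric vector of lick times (s), possibly empty.
#' @export
detect_licks <- function(voltage, sample_rate_hz, threshold,
                         refractory_s = 0.05) {
  stopifnot(sample_rate_hz > 0)
  above <- voltage >= threshold
  rising <- which(above & !c(FALSE, above[-length(above)]))
  if (length(rising) == 0) return(numeric(0))
  times <- (rising - 1) / sample_rate_hz
  keep <- c(TRUE, diff(times) > refractory_s)
  while (!all(keep)) {
    times <- times[keep]
    keep <- c(TRUE, diff(times) > refractory_s)
  }
  times
}

#' Stimulus-evoked lick rate of one trial
#'
#' Default (`mode = "rate"`): licks in the post-stimulus reward window
#' divided by its duration, minus licks in the pre-stimulus window divided by
#' its duration (licks/s) — a per-second comparison that is meaningful when
#' the windows differ in length. `mode = "count"` subtracts raw counts.
#'
#' @param lick_times_s lick times (s), absolute.
#' @param onset_s stimulus onset (s).
#' @param reward_window_s post-stimulus window length (s), default 1.
#' @param pre_window_s pre-stimulus window length (s), default 0.4.
#' @param mode `"rate"` (licks/s, default) or `"count"`.
#' @return the evoked lick-rate difference.
#' @export
lick_rate <- function(lick_times_s, onset_s, reward_window_s = 1,
                      pre_window_s = 0.4, mode = c("rate", "count")) {
  mode <- match.arg(mode)
  rel <- lick_times_s - onset_s
  post <- sum(rel >= 0 & rel < reward_window_s)
  pre <- sum(rel >= -pre_window_s & rel < 0)
  if (mode == "rate") post / reward_window_s - pre / pre_window_s
  else post - pre
}

#' Classify one trial of a go/no-go session
#'
#' Any lick in the `pre_window_s` before onset invalidates the trial.
#' Otherwise a stimulus-present trial is a hit if at least one lick falls in
#' the reward window (else a miss); a catch (0-um) trial with a reward-window
#' lick is a false alarm (else a correct rejection). The response time is
#' the first reward-window lick relative to onset, for hits and false alarms.
#'
#' @param amplitude_um stimulus amplitude (0 = catch trial).
#' @param onset_s stimulus onset (s).
#' @param lick_times_s absolute lick times (s).
#' @param reward_window_s,pre_window_s trial windows (s).
#' @return list with `outcome` (one of `hit`, `miss`, `false_alarm`,
#'   `correct_rejection`, `invalid`) and `response_time_s` (NA unless hit or
#'   false alarm).
#' @export
classify_trial <- function(amplitude_um, onset_s, lick_times_s,
                           reward_window_s = 1, pre_window_s = 0.4) {
  rel <- lick_times_s - onset_s
  if (any(rel >= -pre_window_s & rel < 0)) {
    return(list(outcome = "invalid", response_time_s = NA_real_))
  }
  in_window <- rel[rel >= 0 & rel < reward_window_s]
  responded <- length(in_window) > 0
  outcome <- if (amplitude_um > 0) {
    if (responded) "hit" else "miss"
  } else {
    if (responded) "false_alarm" else "correct_rejection"
  }
  list(outcome = outcome,
       response_time_s = if (responded) in_window[1] else NA_real_)
}

#' Classify every trial of a session
#'
#' @param session behaviour-session tibble (`trial`, `block`, `condition`,
#'   `amplitude_um`, `onset_s`, `lick_times_s` list-column).
#' @param reward_window_s,pre_window_s trial windows (s).
#' @return the session with `outcome`, `response_time_s` and
#'   `lick_rate_diff` (licks/s, see [lick_rate()]) columns appended.
#' @export
classify_trials <- function(session, reward_window_s = 1, pre_window_s = 0.4) {
  res <- mapply(function(a, on, licks) {
    classify_trial(a, on, licks, reward_window_s, pre_window_s)
  }, session$amplitude_um, session$onset_s, session$lick_times_s,
  SIMPLIFY = FALSE)
  session$outcome <- vapply(res, `[[`, character(1), "outcome")
  session$response_time_s <- vapply(res, `[[`, numeric(1), "response_time_s")
  session$lick_rate_diff <- mapply(function(licks, on) {
    lick_rate(licks, on, reward_window_s, pre_window_s)
  }, session$lick_times_s, session$onset_s)
  session
}

#' Detection rate of one block
#'
#' A complete block holds every amplitude exactly once. The block is
#' excluded when its catch trial draws a lick (a false alarm — taken as a
#' lapse of engagement) or cannot be scored (invalid catch, incomplete
#' block). Otherwise the detection rate is the number of hits among the 4
#' stimulus-present trials divided by 4, i.e. one of 0, 0.25, 0.5, 0.75, 1.
#'
#' @param block_trials classified trials of one block (see
#'   [classify_trials()]).
#' @param n_stimuli expected number of stimulus-present trials (default 4).
#' @return list with `block`, `excluded`, `exclusion_reason` and
#'   `detection_rate` (NA when excluded).
#' @export
block_detection_rate <- function(block_trials, n_stimuli = 4) {
  blk <- unique(block_trials$block)
  stopifnot(length(blk) == 1)
  stim <- block_trials[block_trials$amplitude_um > 0, ]
  catch <- block_trials[block_trials$amplitude_um == 0, ]
  if (nrow(stim) != n_stimuli || nrow(catch) != 1) {
    warning(sprintf("block %s incomplete; excluded", blk))
    return(list(block = blk, excluded = TRUE,
                exclusion_reason = "incomplete", detection_rate = NA_real_))
  }
  if (catch$outcome == "false_alarm") {
    return(list(block = blk, excluded = TRUE,
                exclusion_reason = "catch_false_alarm",
                detection_rate = NA_real_))
  }
  if (catch$outcome == "invalid") {
    return(list(block = blk, excluded = TRUE,
                exclusion_reason = "catch_invalid", detection_rate = NA_real_))
  }
  list(block = blk, excluded = FALSE, exclusion_reason = NA_character_,
       detection_rate = sum(stim$outcome == "hit") / n_stimuli)
}

#' Sensitivity index d-prime
#'
#' `d' = qnorm(H) - qnorm(F)` with both rates truncated to `[0.01, 0.99]`
#' before the quantile transform, so d-prime is always finite and bounded by
#' `qnorm(0.99) - qnorm(0.01)` in magnitude.
#'
#' @param hit_rate,fa_rate rates in `[0, 1]` (vectorised).
#' @param floor,ceiling truncation bounds.
#' @return d-prime value(s).
#' @export
d_prime <- function(hit_rate, fa_rate, floor = 0.01, ceiling = 0.99) {
  stopifnot(all(hit_rate >= 0 & hit_rate <= 1),
            all(fa_rate >= 0 & fa_rate <= 1))
  h <- pmin(pmax(hit_rate, floor), ceiling)
  f <- pmin(pmax(fa_rate, floor), ceiling)
  stats::qnorm(h) - stats::qnorm(f)
}

#' Summary of one go/no-go session
#'
#' Classifies all trials and aggregates: per-amplitude lick-rate difference,
#' hit rate and mean response time; the false-alarm rate over all valid
#' catch trials (block exclusion applies to the detection-rate curve only,
#' not to the FA estimate); the per-block detection-rate curve in block
#' order; and the session d-prime from the pooled hit rate over valid
#' stimulus-present trials and the FA rate.
#'
#' @param session behaviour-session tibble.
#' @param reward_window_s,pre_window_s trial windows (s).
#' @return a `session_summary` list: `by_amplitude` tibble, `blocks` tibble
#'   (`block`, `excluded`, `exclusion_reason`, `detection_rate`),
#'   `hit_rate`, `fa_rate`, `d_prime`, `mean_detection_rate`,
#'   `n_blocks_excluded`, `n_invalid_trials`, `condition`.
#' @export
session_summary <- function(session, reward_window_s = 1, pre_window_s = 0.4) {
  cls <- classify_trials(session, reward_window_s, pre_window_s)
  if (all(cls$outcome == "invalid")) stop("no valid trials", call. = FALSE)
  by_amp <- cls |>
    dplyr::group_by(.data$amplitude_um) |>
    dplyr::summarise(
      mean_lick_rate_diff = mean(.data$lick_rate_diff),
      hit_rate = {
        h <- sum(.data$outcome == "hit"); m <- sum(.data$outcome == "miss")
        if (h + m > 0) h / (h + m) else NA_real_
      },
      mean_response_time_s = {
        rt <- .data$response_time_s[.data$outcome %in% c("hit", "false_alarm")]
        if (length(rt) > 0) mean(rt) else NA_real_
      },
      n_trials = dplyr::n(),
      .groups = "drop"
    )
  blocks <- dplyr::bind_rows(lapply(split(cls, cls$block), function(b) {
    as_tibble(block_detection_rate(b))
  }))
  blocks <- blocks[order(blocks$block), ]
  stim <- cls[cls$amplitude_um > 0 & cls$outcome %in% c("hit", "miss"), ]
  catch <- cls[cls$amplitude_um == 0 &
                 cls$outcome %in% c("false_alarm", "correct_rejection"), ]
  if (nrow(stim) == 0 || nrow(catch) == 0) {
    stop("session lacks valid stimulus or catch trials", call. = FALSE)
  }
  hit_rate <- mean(stim$outcome == "hit")
  fa_rate <- mean(catch$outcome == "false_alarm")
  structure(list(
    by_amplitude = by_amp,
    blocks = blocks,
    hit_rate = hit_rate,
    fa_rate = fa_rate,
    d_prime = d_prime(hit_rate, fa_rate),
    mean_detection_rate = mean(blocks$detection_rate, na.rm = TRUE),
    n_blocks_excluded = sum(blocks$excluded),
    n_invalid_trials = sum(cls$outcome == "invalid"),
    condition = unique(cls$condition)[1]
  ), class = "session_summary")
}
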