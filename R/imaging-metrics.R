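#' Neuropil correction of ROI fluorescence
#'
#' Subtracts the background neuropil signal from every ROI trace. The default
#' subtracts the scalar session mean of the neuropil trace; the frame-wise
#' option subtracts `r * neuropil(t)` per frame, which also removes shared
#' contamination dynamics.
#'
#' @param traces a `roi_trace_set` (fields `F`, `neuropil`, `frame_times_s`,
#'   `onsets`, ...).
#' @param method `"scalar"` (subtract the neuropil mean) or `"framewise"`
#'   (subtract `r * neuropil(t)`).
#' @param r contamination coefficient for the frame-wise method.
#' @return the trace set with corrected `F` and a `neuropil_correction`
#'   record appended.
#' @export
neuropil_correct <- function(traces, method = c("scalar", "framewise"), r = 0.7) {
  method <- match.arg(method)
  stopifnot(inherits(traces, "roi_trace_set"))
  if (length(traces$neuropil) != ncol(traces$F)) {
    stop("neuropil trace and ROI matrix must have matching frame counts",
         call. = FALSE)
  }
  corrected <- traces
  if (method == "scalar") {
    corrected$F <- traces$F - mean(traces$neuropil)
  } else {
    corrected$F <- sweep(traces$F, 2, r * traces$neuropil)
  }
  corrected$neuropil_correction <- list(method = method,
                                        r = if (method == "framewise") r else NA,
                                        neuropil_mean = mean(traces$neuropil))
  corrected
}

#' Fractional fluorescence change (dF/F0)
#'
#' Computes `dF/F0 = (F - F0) / F0` frame-wise per ROI, with `F0` the mean
#' of the (corrected) trace over the whole recording session. With this
#' baseline the session mean of each ROI's dF/F0 is exactly 0. ROIs whose
#' `F0` is not positive are excluded with a warning.
#'
#' @param traces a (typically neuropil-corrected) `roi_trace_set`.
#' @return a `dff_set`: fields `dff` (ROI x frame), `f0` (per ROI),
#'   `frame_times_s`, `onsets`, `condition`, `roi_ids`, `excluded_rois`.
#' @export
compute_dff <- function(traces) {
  stopifnot(inherits(traces, "roi_trace_set"))
  f0 <- rowMeans(traces$F)
  bad <- f0 <= 0
  if (any(bad)) {
    warning(sprintf("%d ROI(s) excluded: non-positive F0", sum(bad)))
  }
  keep <- !bad
  structure(list(
    dff = sweep(traces$F[keep, , drop = FALSE], 1, f0[keep]) / f0[keep],
    f0 = f0[keep],
    frame_times_s = traces$frame_times_s,
    onsets = traces$onsets,
    condition = traces$condition,
    roi_ids = traces$roi_ids[keep],
    excluded_rois = traces$roi_ids[bad]
  ), class = "dff_set")
}

# Per-trial evoked dF/F values: mean over [onset, onset + window) minus
# (optionally) the mean over [onset - pre_window, onset). Returns a tibble
# roi x trial; trials whose post window overruns the recording are dropped.
trialwise_evoked <- function(dff, window_s, pre_window_s, subtract_pre) {
  ft <- dff$frame_times_s
  rows <- list()
  dropped <- 0L
  for (i in seq_len(nrow(dff$onsets))) {
    on <- dff$onsets$onset_s[i]
    post_idx <- which(ft >= on & ft < on + window_s)
    pre_idx <- which(ft >= on - pre_window_s & ft < on)
    if (length(post_idx) == 0 || max(ft) < on + window_s) {
      dropped <- dropped + 1L
      next
    }
    post <- rowMeans(dff$dff[, post_idx, drop = FALSE])
    pre <- if (length(pre_idx) > 0) {
      rowMeans(dff$dff[, pre_idx, drop = FALSE])
    } else {
      rep(0, nrow(dff$dff))
    }
    rows[[length(rows) + 1]] <- tibble(
      roi = dff$roi_ids,
      onset_index = i,
      amplitude_um = dff$onsets$amplitude_um[i],
      pre_dff = pre,
      post_dff = post,
      evoked_dff = if (subtract_pre) post - pre else post
    )
  }
  if (dropped > 0) {
    warning(sprintf("%d onset(s) dropped: post window exceeds the recording",
                    dropped))
  }
  if (length(rows) == 0) stop("no usable onsets", call. = FALSE)
  dplyr::bind_rows(rows)
}

#' Evoked dF/F0 responses
#'
#' Per trial, the evoked response is the mean dF/F0 over a 1-s post-stimulus
#' window minus the mean over a matched pre-stimulus window; responses are
#' then averaged per ROI x amplitude.
#'
#' @param dff a `dff_set`.
#' @param window_s post-stimulus window (s), default 1.
#' @param pre_window_s pre-stimulus baseline window (s), default equal to
#'   `window_s`.
#' @param subtract_pre subtract the pre-window mean (default TRUE).
#' @return tibble with `roi`, `condition`, `amplitude_um`, `mean_evoked_dff`,
#'   `sem_evoked_dff`, `n_trials`.
#' @export
evoked_dff <- function(dff, window_s = 1, pre_window_s = window_s,
                       subtract_pre = TRUE) {
  stopifnot(inherits(dff, "dff_set"), window_s > 0)
  tw <- trialwise_evoked(dff, window_s, pre_window_s, subtract_pre)
  tw |>
    dplyr::group_by(.data$roi, .data$amplitude_um) |>
    dplyr::summarise(
      mean_evoked_dff = mean(.data$evoked_dff),
      sem_evoked_dff = sem(.data$evoked_dff),
      n_trials = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(condition = dff$condition, .after = "roi")
}

#' Classify sensory-responsive ROIs
#'
#' An ROI is responsive under a condition if the paired t-test of trial-wise
#' post-stimulus vs pre-stimulus mean dF/F0 is significant at `alpha`. By
#' default only stimulus-present trials enter the comparison.
#'
#' @param dff a `dff_set` (one condition).
#' @param window_s,pre_window_s comparison windows (s).
#' @param alpha significance level.
#' @param stim_only use only amplitude > 0 onsets when available.
#' @return tibble with `roi`, `condition`, `p_value`, `responsive`, plus the
#'   attribute `fraction_responsive`.
#' @export
classify_responsive_rois <- function(dff, window_s = 1, pre_window_s = 1,
                                     alpha = 0.05, stim_only = TRUE) {
  stopifnot(inherits(dff, "dff_set"))
  tw <- trialwise_evoked(dff, window_s, pre_window_s, subtract_pre = FALSE)
  if (stim_only && any(tw$amplitude_um > 0)) {
    tw <- tw[tw$amplitude_um > 0, ]
  }
  out <- tw |>
    dplyr::group_by(.data$roi) |>
    dplyr::summarise(
      p_value = paired_t(.data$post_dff, .data$pre_dff)$p_value,
      n_trials = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(condition = dff$condition, .after = "roi") |>
    dplyr::mutate(responsive = .data$p_value < alpha)
  attr(out, "fraction_responsive") <- mean(out$responsive)
  out
}

#' Population heatmap ordering
#'
#' ROI display order for population heatmaps: descending evoked response in
#' a reference condition, with the same order then applied to the other
#' conditions. Ties are broken by ROI id for determinism.
#'
#' @param evoked an [evoked_dff()] table for the reference condition.
#' @param amplitude_um amplitude whose response defines the order (default:
#'   highest present).
#' @return integer vector of ROI ids in display order.
#' @export
sort_population_heatmap <- function(evoked, amplitude_um = NULL) {
  if (is.null(amplitude_um)) amplitude_um <- max(evoked$amplitude_um)
  sub <- evoked[evoked$amplitude_um == amplitude_um, ]
  if (nrow(sub) == 0) stop("no rows at the requested amplitude", call. = FALSE)
  sub$roi[order(-sub$mean_evoked_dff, sub$roi)]
}
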