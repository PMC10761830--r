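#' Stimulus-free (spontaneous) segments of a recording
#'
#' Returns the frame-index segments that lie outside every stimulus response
#' epoch `[onset - pre_margin_s, onset + post_margin_s)`. Segments are kept
#' separate so that downstream correlations never span a splice.
#'
#' @param frame_times_s frame times (s), strictly increasing.
#' @param onsets_s stimulus onset times (s); may be empty.
#' @param pre_margin_s margin excluded before each onset (s).
#' @param post_margin_s margin excluded after each onset (s), covering the
#'   response window and indicator decay.
#' @return list of integer vectors (consecutive frame indices); errors if no
#'   spontaneous frames remain.
#' @export
spontaneous_segments <- function(frame_times_s, onsets_s,
                                 pre_margin_s = 0.5, post_margin_s = 3) {
  stopifnot(!is.unsorted(frame_times_s, strictly = TRUE))
  keep <- rep(TRUE, length(frame_times_s))
  for (on in onsets_s) {
    keep[frame_times_s >= on - pre_margin_s &
           frame_times_s < on + post_margin_s] <- FALSE
  }
  if (!any(keep)) stop("no spontaneous frames outside stimulus epochs", call. = FALSE)
  idx <- which(keep)
  brk <- c(0, which(diff(idx) > 1), length(idx))
  lapply(seq_len(length(brk) - 1), function(i) idx[(brk[i] + 1):brk[i + 1]])
}

#' Normalised cross-correlogram of two signals
#'
#' Both signals are mean-centred over the analysed frames and the lagged
#' cross-products are normalised by the geometric mean of the zero-lag
#' autocorrelations, so each autocorrelogram equals 1 at lag 0 and the
#' cross-correlogram value at lag 0 equals the Pearson correlation
#' coefficient. All values are bounded by 1 in magnitude; negative
#' correlations are retained, not clipped. When segments are supplied, no
#' lagged product ever spans a segment boundary.
#'
#' @param x,y equal-length numeric signals (at least 100 samples).
#' @param dt_s sampling interval (s).
#' @param max_lag_s maximum lag (s), default 2.
#' @param segments optional list of index segments (see
#'   [spontaneous_segments()]); default: one segment covering everything.
#' @return a `correlogram` list: `lags_s`, `values`, `strength` (the lag-0
#'   value), `zero_variance` flag (strength set to 0 when either signal has
#'   zero variance).
#' @export
cross_correlogram <- function(x, y, dt_s, max_lag_s = 2, segments = NULL) {
  stopifnot(length(x) == length(y))
  if (is.null(segments)) segments <- list(seq_along(x))
  use <- unlist(segments)
  if (length(use) < 100) stop("need at least 100 samples", call. = FALSE)
  mx <- mean(x[use]); my <- mean(y[use])
  xc <- x - mx; yc <- y - my
  ssx <- sum(xc[use]^2); ssy <- sum(yc[use]^2)
  max_lag <- floor(max_lag_s / dt_s)
  lags <- -max_lag:max_lag
  zero_var <- ssx == 0 || ssy == 0
  if (zero_var) {
    vals <- rep(0, length(lags))
  } else {
    denom <- sqrt(ssx * ssy)
    vals <- vapply(lags, function(l) {
      s <- 0
      for (seg in segments) {
        n <- length(seg)
        if (n <= abs(l)) next
        if (l >= 0) {
          i <- seg[seq_len(n - l)]
          s <- s + sum(xc[i] * yc[i + l])
        } else {
          i <- seg[seq_len(n + l)]
          s <- s + sum(xc[i - l] * yc[i])
        }
      }
      s / denom
    }, numeric(1))
  }
  structure(list(lags_s = lags * dt_s, values = vals,
                 strength = vals[lags == 0], zero_variance = zero_var),
            class = "correlogram")
}

#' Pairwise noise-correlation matrix
#'
#' Lag-0 correlogram strength for every unordered ROI pair (i < j), computed
#' over spontaneous segments. Because lag-0 products never span a splice,
#' the strength equals the Pearson correlation over the concatenated
#' spontaneous frames, which is how it is computed here; [cross_correlogram()]
#' gives the identical value together with the full lag profile.
#'
#' @param dff a `dff_set`, or a plain numeric matrix (units x frames) with
#'   `frame_times_s` supplied.
#' @param pre_margin_s,post_margin_s spontaneous-segment margins, passed to
#'   [spontaneous_segments()].
#' @param frame_times_s,onsets_s,condition used when `dff` is a bare matrix.
#' @return a `correlation_matrix` list: `pairs` tibble (`i`, `j`,
#'   `condition`, `strength`), `mean_strength`, `sem_strength`,
#'   `n_pairs`, `n_frames`.
#' @export
pairwise_matrix <- function(dff, pre_margin_s = 0.5, post_margin_s = 3,
                            frame_times_s = NULL, onsets_s = NULL,
                            condition = NA_character_) {
  if (inherits(dff, "dff_set")) {
    mat <- dff$dff
    frame_times_s <- dff$frame_times_s
    onsets_s <- dff$onsets$onset_s
    condition <- dff$condition
    ids <- dff$roi_ids
  } else {
    mat <- dff
    if (is.null(frame_times_s)) stop("`frame_times_s` required", call. = FALSE)
    if (is.null(onsets_s)) onsets_s <- numeric(0)
    ids <- seq_len(nrow(mat))
  }
  if (nrow(mat) < 2) stop("need at least 2 units", call. = FALSE)
  segs <- spontaneous_segments(frame_times_s, onsets_s,
                               pre_margin_s, post_margin_s)
  use <- unlist(segs)
  cm <- stats::cor(t(mat[, use, drop = FALSE]))
  ut <- which(upper.tri(cm), arr.ind = TRUE)
  pairs <- tibble(
    i = ids[ut[, 1]], j = ids[ut[, 2]], condition = condition,
    strength = cm[ut]
  )
  structure(list(
    pairs = pairs,
    mean_strength = mean(pairs$strength),
    sem_strength = sem(pairs$strength),
    n_pairs = nrow(pairs),
    n_frames = length(use)
  ), class = "correlation_matrix")
}

#' Joint peristimulus time histogram with shift predictor
#'
#' Bin-by-bin coincidence matrix for a neuron pair:
#' `raw[b1, b2] = mean over trials of count_i(b1) * count_j(b2)`. The shift
#' predictor repeats the computation with the trials of neuron j rotated by
#' one, removing all stimulus-locked (signal) structure; the corrected
#' matrix `raw - predictor` isolates trial-by-trial (noise) coupling.
#'
#' @param spikes_i,spikes_j lists of per-trial spike-time vectors (matched
#'   trial counts, >= 2 trials, common time base).
#' @param bin_s bin width (s).
#' @param window_s analysis window `c(from, to)` (s).
#' @return a `jpsth` list: `raw`, `predictor`, `corrected` (bin x bin
#'   matrices, rows = neuron i), `bin_edges_s`, `bin_s`.
#' @export
jpsth <- function(spikes_i, spikes_j, bin_s = 0.005, window_s = c(-0.05, 0.1)) {
  n_tr <- length(spikes_i)
  if (n_tr != length(spikes_j)) stop("trial counts must match", call. = FALSE)
  if (n_tr < 2) stop("need at least 2 trials", call. = FALSE)
  edges <- seq(window_s[1], window_s[2], by = bin_s)
  nb <- length(edges) - 1
  bin_counts <- function(trains) {
    t(vapply(trains, function(s) {
      if (length(s) == 0) return(numeric(nb))
      h <- findInterval(s, edges, rightmost.closed = FALSE)
      tabulate(h[h >= 1 & h <= nb], nbins = nb)
    }, numeric(nb)))
  }
  ci <- bin_counts(spikes_i)
  cj <- bin_counts(spikes_j)
  raw <- crossprod(ci, cj) / n_tr
  cj_shift <- cj[c(2:n_tr, 1), , drop = FALSE]
  predictor <- crossprod(ci, cj_shift) / n_tr
  structure(list(raw = raw, predictor = predictor,
                 corrected = raw - predictor,
                 bin_edges_s = edges, bin_s = bin_s),
            class = "jpsth")
}
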