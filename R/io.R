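#' Write a trial raster to the spikes CSV schema
#'
#' Long format, one row per spike (`neuron_id`, `condition`, `amplitude_um`,
#' `trial`, `spike_time_s`); trials without spikes are preserved as a row
#' with an empty `spike_time_s` field so the round trip is lossless.
#' UTF-8, header row, `.` decimal, times in seconds, amplitudes in um.
#'
#' @param raster trial raster tibble with a `spike_times_s` list-column.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spikes_csv <- function(raster, path) {
  long <- raster |>
    dplyr::mutate(spike_time_s = lapply(.data$spike_times_s, function(s) {
      if (length(s) == 0) NA_real_ else s
    })) |>
    dplyr::select(-"spike_times_s") |>
    tidyr::unnest("spike_time_s")
  utils::write.csv(long, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a spikes CSV back into a trial raster
#'
#' @param path CSV written by [write_spikes_csv()].
#' @return trial raster tibble with sorted `spike_times_s` list-column.
#' @export
read_spikes_csv <- function(path) {
  long <- utils::read.csv(path, fileEncoding = "UTF-8")
  required <- c("neuron_id", "condition", "amplitude_um", "trial", "spike_time_s")
  missing <- setdiff(required, names(long))
  if (length(missing) > 0) {
    stop("spikes CSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(long$amplitude_um)) {
    bad <- which(is.na(suppressWarnings(as.numeric(long$amplitude_um))))[1]
    stop(sprintf("column 'amplitude_um' is not numeric (first bad row: %d)", bad),
         call. = FALSE)
  }
  long |>
    dplyr::group_by(.data$neuron_id, .data$condition, .data$amplitude_um,
                    .data$trial) |>
    dplyr::summarise(
      spike_times_s = list(sort(.data$spike_time_s[!is.na(.data$spike_time_s)])),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$neuron_id, .data$condition, .data$amplitude_um,
                   .data$trial)
}

#' Write a behaviour session to CSV
#'
#' One row per trial; `lick_times_s` is a JSON-encoded list so the variable
#' number of licks per trial survives the round trip.
#'
#' @param session behaviour-session tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_behavior_csv <- function(session, path) {
  out <- session |>
    dplyr::mutate(lick_times_s = vapply(.data$lick_times_s, function(l) {
      as.character(jsonlite::toJSON(l, digits = NA))
    }, character(1)))
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a behaviour session CSV
#'
#' @param path CSV written by [write_behavior_csv()].
#' @return behaviour-session tibble with a `lick_times_s` list-column.
#' @export
read_behavior_csv <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  required <- c("trial", "block", "condition", "amplitude_um", "onset_s",
                "lick_times_s")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("behaviour CSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$lick_times_s <- lapply(df$lick_times_s, function(j) {
    as.numeric(jsonlite::fromJSON(j))
  })
  as_tibble(df)
}

#' Write a fluorescence trace set to a plain-text container
#'
#' Directory layout (one directory per condition): `traces.csv` (ROI x
#' frame matrix, one row per ROI), `neuropil.csv`, `frame_times.csv`,
#' `onsets.csv` and `meta.json` (condition label and ROI ids).
#'
#' @param traces a `roi_trace_set`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_traces_dir <- function(traces, dir) {
  stopifnot(inherits(traces, "roi_trace_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(traces$F), file.path(dir, "traces.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(data.frame(neuropil = traces$neuropil),
                   file.path(dir, "neuropil.csv"), row.names = FALSE,
                   fileEncoding = "UTF-8")
  utils::write.csv(data.frame(frame_time_s = traces$frame_times_s),
                   file.path(dir, "frame_times.csv"), row.names = FALSE,
                   fileEncoding = "UTF-8")
  utils::write.csv(traces$onsets, file.path(dir, "onsets.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  jsonlite::write_json(
    list(condition = traces$condition, roi_ids = traces$roi_ids),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a fluorescence trace container
#'
#' @param dir directory written by [write_traces_dir()].
#' @return a `roi_trace_set`.
#' @export
read_traces_dir <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  f <- as.matrix(utils::read.csv(file.path(dir, "traces.csv"),
                                 fileEncoding = "UTF-8"))
  dimnames(f) <- NULL
  structure(list(
    F = f,
    neuropil = utils::read.csv(file.path(dir, "neuropil.csv"),
                               fileEncoding = "UTF-8")$neuropil,
    frame_times_s = utils::read.csv(file.path(dir, "frame_times.csv"),
                                    fileEncoding = "UTF-8")$frame_time_s,
    onsets = as_tibble(utils::read.csv(file.path(dir, "onsets.csv"),
                                       fileEncoding = "UTF-8")),
    condition = meta$condition,
    roi_ids = meta$roi_ids
  ), class = "roi_trace_set")
}

#' Write ground truth as a JSON sidecar
#'
#' @param ground_truth a simulator `ground_truth` list.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a ground-truth JSON sidecar
#'
#' @param path JSON written by [write_ground_truth_json()].
#' @return list of tibbles.
#' @export
read_ground_truth_json <- function(path) {
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(gt, function(x) if (is.list(x) || is.data.frame(x)) as_tibble(x) else x)
}
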