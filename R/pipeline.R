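#' Configuration for the full synthetic study
#'
#' Bundles the three arm configurations (electrophysiology, imaging,
#' behaviour) together with the analysis constants: 50-ms evoked rate
#' window, 100-ms latency window, 1-s imaging window, 400-ms pre-lick
#' window, 1-s reward window and alpha = 0.05.
#'
#' @param ephys an [ephys_sim_config()].
#' @param imaging an [imaging_sim_config()].
#' @param behavior a [behavior_sim_config()].
#' @param n_behavior_sessions behavioural sessions per condition (the study
#'   design repeats each condition 5 times).
#' @param rate_window_s,latency_window_s,imaging_window_s analysis windows (s).
#' @param alpha significance level.
#' @param control control condition label.
#' @return a `study_config` list.
#' @export
study_config <- function(ephys = ephys_sim_config(n_neurons = 12),
                         imaging = imaging_sim_config(n_rois = 15,
                                                      trials_per_amplitude = 10),
                         behavior = behavior_sim_config(),
                         n_behavior_sessions = 5,
                         rate_window_s = 0.05,
                         latency_window_s = 0.1,
                         imaging_window_s = 1,
                         alpha = 0.05,
                         control = "aCSF") {
  stopifnot(rate_window_s > 0, latency_window_s > 0, imaging_window_s > 0,
            alpha > 0, alpha < 1, n_behavior_sessions >= 1)
  structure(list(ephys = ephys, imaging = imaging, behavior = behavior,
                 n_behavior_sessions = n_behavior_sessions,
                 rate_window_s = rate_window_s,
                 latency_window_s = latency_window_s,
                 imaging_window_s = imaging_window_s,
                 alpha = alpha, control = control),
            class = "study_config")
}

#' Run the full synthetic three-condition study
#'
#' Generates the three synthetic datasets, runs every analysis arm and the
#' comparison layer, and returns a report bundle of tidy tables. The whole
#' run is deterministic for a given seed (the seed reseeds each arm's
#' config), and the bundle records the seed and a hash of the configuration
#' for provenance.
#'
#' @param config a [study_config()].
#' @param seed integer master seed; each arm derives its own sub-seed.
#' @return a `report_bundle` list of tibbles: `ephys_rates`,
#'   `ephys_scalars`, `ephys_latency`, `ephys_fano`, `gain_fits`,
#'   `gain_summary`, `ephys_stats`, `imaging_evoked`, `imaging_fractions`,
#'   `correlation_pairs`, `correlation_summary`, `correlation_stats`,
#'   `behavior_sessions`, `behavior_stats`, and `provenance`.
#' @export
run_full_synthetic_study <- function(config = study_config(), seed = 1) {
  stopifnot(inherits(config, "study_config"))
  seed <- as.integer(seed)
  ecfg <- config$ephys;  ecfg$seed <- seed
  icfg <- config$imaging; icfg$seed <- seed + 1L
  ctl <- config$control

  # --- electrophysiology arm ---
  eph <- simulate_spike_trains(ecfg)
  rates <- evoked_rate(eph$raster, config$rate_window_s)
  scalars <- response_scalars(rates)
  latency <- first_spike_latency(eph$raster, window_s = config$latency_window_s)
  top_amp <- max(eph$raster$amplitude_um)
  fano <- fano_by_amplitude(eph$raster, config$rate_window_s)
  fano_top <- fano[fano$amplitude_um == top_amp, ]
  fits <- gain_table(rates, control = ctl)
  gain_sum <- population_gain_summary(fits)
  ephys_stats <- dplyr::bind_rows(
    compare_conditions(
      dplyr::transmute(scalars, subject = .data$neuron_id,
                       condition = .data$condition,
                       value = .data$max_evoked_hz),
      metric = "max_evoked_hz"),
    compare_conditions(
      dplyr::transmute(scalars, subject = .data$neuron_id,
                       condition = .data$condition,
                       value = .data$baseline_hz),
      metric = "baseline_hz"),
    compare_conditions(
      dplyr::transmute(latency, subject = .data$neuron_id,
                       condition = .data$condition,
                       value = .data$mean_latency_s),
      metric = "first_spike_latency_s"),
    compare_conditions(
      dplyr::transmute(fano_top, subject = .data$neuron_id,
                       condition = .data$condition, value = .data$fano),
      metric = "fano_top_amplitude")
  )

  # --- imaging arm ---
  img <- simulate_population_traces(icfg)
  dffs <- lapply(img$traces, function(ts) compute_dff(neuropil_correct(ts)))
  evoked <- dplyr::bind_rows(lapply(dffs, function(d) {
    evoked_dff(d, window_s = config$imaging_window_s)
  }))
  fractions <- dplyr::bind_rows(lapply(dffs, function(d) {
    cls <- classify_responsive_rois(d, window_s = config$imaging_window_s,
                                    alpha = config$alpha)
    tibble(condition = d$condition,
           fraction_responsive = attr(cls, "fraction_responsive"),
           n_rois = nrow(cls))
  }))
  pair_mats <- lapply(dffs, pairwise_matrix)
  pairs <- dplyr::bind_rows(lapply(pair_mats, function(pm) pm$pairs))
  corr_summary <- dplyr::bind_rows(lapply(pair_mats, function(pm) {
    tibble(condition = pm$pairs$condition[1], mean_strength = pm$mean_strength,
           sem_strength = pm$sem_strength, n_pairs = pm$n_pairs)
  }))
  corr_stats <- compare_conditions(
    dplyr::transmute(pairs, subject = paste(.data$i, .data$j, sep = "-"),
                     condition = .data$condition, value = .data$strength),
    metric = "pairwise_noise_correlation")

  # --- behaviour arm ---
  bcfg <- config$behavior
  beh_rows <- list()
  for (s in seq_len(config$n_behavior_sessions)) {
    bcfg$seed <- seed + 100L + s
    sim <- simulate_behavior_session(bcfg)
    for (cn in names(sim$sessions)) {
      ss <- session_summary(sim$sessions[[cn]],
                            reward_window_s = bcfg$reward_window_s,
                            pre_window_s = bcfg$pre_window_s)
      beh_rows[[length(beh_rows) + 1]] <- tibble(
        session = s, condition = cn, hit_rate = ss$hit_rate,
        fa_rate = ss$fa_rate, d_prime = ss$d_prime,
        mean_detection_rate = ss$mean_detection_rate,
        n_blocks_excluded = ss$n_blocks_excluded
      )
    }
  }
  behavior_sessions <- dplyr::bind_rows(beh_rows)
  behavior_stats <- dplyr::bind_rows(
    compare_conditions(
      dplyr::transmute(behavior_sessions, subject = .data$session,
                       condition = .data$condition, value = .data$d_prime),
      metric = "d_prime"),
    compare_conditions(
      dplyr::transmute(behavior_sessions, subject = .data$session,
                       condition = .data$condition,
                       value = .data$mean_detection_rate),
      metric = "mean_detection_rate")
  )

  structure(list(
    ephys_rates = rates, ephys_scalars = scalars, ephys_latency = latency,
    ephys_fano = fano, gain_fits = fits, gain_summary = gain_sum,
    ephys_stats = ephys_stats, imaging_evoked = evoked,
    imaging_fractions = fractions, correlation_pairs = pairs,
    correlation_summary = corr_summary, correlation_stats = corr_stats,
    behavior_sessions = behavior_sessions, behavior_stats = behavior_stats,
    provenance = tibble(
      seed = seed,
      config_hash = rlang::hash(config),
      package_version = as.character(utils::packageVersion("sensorygain"))
    )
  ), class = "report_bundle")
}

#' Write a report bundle to a directory of CSV files
#'
#' @param bundle a `report_bundle`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(bundle)) {
    tbl <- bundle[[nm]]
    if (is.data.frame(tbl)) {
      flat <- tbl[, !vapply(tbl, is.list, logical(1)), drop = FALSE]
      utils::write.csv(flat, file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE, fileEncoding = "UTF-8")
    }
  }
  invisible(dir)
}
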