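#' Score all four metrics against a network's ground truth
#'
#' For each pairwise measure: Spearman correlation with the resource overlap,
#' link-detection AUC (positive overlap as truth), and guild-detection AUC
#' (single-linkage clustering against the true guild labels).
#'
#' @param metrics A [pairwise_metrics()] list.
#' @param network The generating `resource_network`.
#' @param mode Clustering mode for guild detection.
#' @param n_thresholds Sweep size for the ROCs.
#' @return A tibble with one row per metric: `metric`, `spearman_rho`,
#'   `spearman_p`, `link_auc`, `guild_auc`.
#' @export
evaluate_metrics <- function(metrics, network, mode = "full",
                             n_thresholds = 200) {
  purrr::map_dfr(names(metrics), function(nm) {
    m <- metrics[[nm]]
    sp <- spearman_vs_overlap(m, network$overlap)
    tibble::tibble(
      metric = nm,
      spearman_rho = sp$rho,
      spearman_p = sp$p_value,
      link_auc = link_roc(m, network$overlap, n_thresholds)$auc,
      guild_auc = guild_roc(m, network$guild_labels, mode, n_thresholds)$auc)
  })
}

# One simulated realization: network + drive + trajectory, returned with the
# z-scored series at the requested sampling interval.
simulate_realization <- function(config, drive_kind, drive_args, params, seed) {
  cfg <- config
  cfg$seed <- derive_seed(seed, "network")
  full_cfg <- do.call(guild_config, cfg)
  net <- sample_network(full_cfg)
  drv <- do.call(drive_spec, c(list(kind = drive_kind,
                                    n_resources = full_cfg$n_resources,
                                    seed = derive_seed(seed, "drive")),
                               drive_args))
  traj <- simulate_ecrm(net, drv, params, seed = derive_seed(seed, "sim"))
  list(network = net, drive = drv, trajectory = traj)
}

#' Run a replicated guild-inference experiment on simulated communities
#'
#' For each realization: draw a fresh guild-structured network, simulate the
#' consumer-resource dynamics under the chosen drive, sample the abundances,
#' log-z-score them, compute the four pairwise measures, and score each
#' against the ground truth.
#'
#' @param n_realizations Number of independent network + drive realizations.
#' @param network Named list of [guild_config()] arguments (e.g.
#'   `list(n_species = 6, n_resources = 30, n_guilds = 2, guild_bias = 0.4)`).
#' @param drive_kind `"ou"`, `"sinusoidal"`, or `"constant"`.
#' @param drive Named list of extra [drive_spec()] arguments (e.g.
#'   `list(frequency = 1)` or `list(omega_range = c(1, 10))`).
#' @param params A [sim_params()].
#' @param sampling_interval Abundance sampling interval for the analysis.
#' @param mode Clustering mode for guild detection.
#' @param seed Root seed; realizations use derived independent streams.
#' @param n_thresholds ROC sweep size.
#' @return A tibble: one row per realization and metric with Spearman rho/p,
#'   link AUC, and guild AUC.
#' @export
#' @examples
#' \donttest{
#' res <- run_guild_experiment(2, network = list(guild_bias = 0.4),
#'                             params = sim_params(t_final = 500), seed = 1)
#' }
run_guild_experiment <- function(n_realizations,
                                 network = list(),
                                 drive_kind = "ou",
                                 drive = list(frequency = 1),
                                 params = sim_params(),
                                 sampling_interval = params$sampling_interval,
                                 mode = "full",
                                 seed = 1,
                                 n_thresholds = 200) {
  purrr::map_dfr(seq_len(n_realizations), function(r) {
    rs <- derive_seed(seed, paste0("realization-", r))
    real <- simulate_realization(network, drive_kind, drive, params, rs)
    series <- sample_series(real$trajectory, sampling_interval)
    mets <- pairwise_metrics(log_zscore(series), sampling_interval)
    out <- evaluate_metrics(mets, real$network, mode, n_thresholds)
    out$realization <- r
    out
  })
}

#' Sweep the sampling interval at fixed acquisition time
#'
#' Simulates each realization once on a fine record grid and re-analyzes the
#' same trajectory at every requested sampling interval, scoring the four
#' measures at each. This isolates the effect of the sampling rate from that
#' of the realization.
#'
#' @inheritParams run_guild_experiment
#' @param sampling_intervals Vector of intervals (each a multiple of the
#'   trajectory record grid).
#' @return A tibble: one row per realization, sampling interval and metric.
#' @export
sweep_sampling_intervals <- function(n_realizations,
                                     sampling_intervals = c(0.25, 0.5, 1, 2, 4, 8),
                                     network = list(),
                                     drive_kind = "ou",
                                     drive = list(frequency = 1),
                                     params = sim_params(),
                                     mode = "full",
                                     seed = 1,
                                     n_thresholds = 200) {
  ratios <- sampling_intervals / params$record_interval
  stopifnot(all(abs(ratios - round(ratios)) < 1e-8))
  purrr::map_dfr(seq_len(n_realizations), function(r) {
    rs <- derive_seed(seed, paste0("realization-", r))
    real <- simulate_realization(network, drive_kind, drive, params, rs)
    purrr::map_dfr(sampling_intervals, function(dt) {
      series <- sample_series(real$trajectory, dt)
      mets <- pairwise_metrics(log_zscore(series), dt)
      out <- evaluate_metrics(mets, real$network, mode, n_thresholds)
      out$realization <- r
      out$sampling_interval <- dt
      out
    })
  })
}

# Truncate a recorded trajectory to an earlier final time.
truncate_trajectory <- function(traj, t_final) {
  keep <- traj$times <= t_final + 1e-9
  traj$times <- traj$times[keep]
  traj$abundances <- traj$abundances[, keep, drop = FALSE]
  traj$resources <- traj$resources[, keep, drop = FALSE]
  traj$drive_realization <- traj$drive_realization[, keep, drop = FALSE]
  traj
}

#' Guild-detection AUC over an acquisition-time by sampling-interval grid
#'
#' Each realization is simulated once up to the longest acquisition time and
#' truncated to every shorter one, so the grid varies only data duration and
#' sampling rate, never the community. At each grid cell the guild-detection
#' AUC of the requested spectral measures is computed either by pooling pair
#' predictions across realizations into one ROC ([pooled_guild_roc()]) or by
#' averaging per-realization AUCs. Cells whose sampled series are too short
#' for the Welch frequency resolution are returned as `NA`.
#'
#' @inheritParams run_guild_experiment
#' @param acquisition_times Vector of final times t_f (truncations of one run).
#' @param sampling_intervals Vector of sampling intervals (multiples of the
#'   record grid).
#' @param pooled Pool pairs across realizations into one ROC per cell
#'   (default), or average per-realization AUCs.
#' @param metrics Which pairwise measures to score.
#' @return A tibble with one row per acquisition time, sampling interval and
#'   metric: `t_final`, `sampling_interval`, `metric`, `guild_auc` (`NA` when
#'   infeasible), `n_realizations`.
#' @export
sweep_acquisition_grid <- function(n_realizations,
                                   acquisition_times,
                                   sampling_intervals = c(0.25, 0.5, 1, 2, 4, 8),
                                   network = list(),
                                   drive_kind = "ou",
                                   drive = list(frequency = 1),
                                   params = sim_params(t_final = max(acquisition_times)),
                                   mode = "full",
                                   pooled = TRUE,
                                   seed = 1,
                                   n_thresholds = 200,
                                   metrics = c("total_cpsd", "total_coherence")) {
  stopifnot(params$t_final >= max(acquisition_times))
  reals <- lapply(seq_len(n_realizations), function(r) {
    rs <- derive_seed(seed, paste0("realization-", r))
    simulate_realization(network, drive_kind, drive, params, rs)
  })
  purrr::map_dfr(acquisition_times, function(tf) {
    purrr::map_dfr(sampling_intervals, function(dt) {
      cells <- lapply(reals, function(real) {
        tr <- truncate_trajectory(real$trajectory, tf)
        tryCatch(
          pairwise_metrics(log_zscore(sample_series(tr, dt)), dt)[metrics],
          error = function(e) NULL)
      })
      ok <- !vapply(cells, is.null, logical(1))
      purrr::map_dfr(metrics, function(nm) {
        auc <- if (!any(ok)) NA_real_
        else if (pooled) {
          pooled_guild_roc(lapply(cells[ok], `[[`, nm),
                           lapply(reals[ok], function(r) r$network$guild_labels),
                           mode, n_thresholds)$auc
        } else {
          mean(vapply(which(ok), function(r)
            guild_roc(cells[[r]][[nm]], reals[[r]]$network$guild_labels,
                      mode, n_thresholds)$auc, numeric(1)))
        }
        tibble::tibble(t_final = tf, sampling_interval = dt, metric = nm,
                       guild_auc = auc, n_realizations = sum(ok))
      })
    })
  })
}

#' Sampling interval maximizing the mean guild-detection AUC
#'
#' Averages the guild AUC of [sweep_acquisition_grid()] over the acquisition
#' times for one metric (infeasible cells count as chance level) and returns
#' the sampling interval attaining the maximum.
#'
#' @param results A [sweep_acquisition_grid()] tibble.
#' @param metric Metric name to optimize.
#' @param chance_level AUC substituted for infeasible cells (default 0.5).
#' @return A list with `best_interval` and the per-interval `means` tibble.
#' @export
optimal_sampling_interval <- function(results, metric, chance_level = 0.5) {
  sub <- results[results$metric == metric, ]
  if (nrow(sub) == 0)
    stop_ecoguilds("metric ", metric, " not present in the sweep results",
                   class = "ecoguilds_data_error")
  sub$guild_auc[is.na(sub$guild_auc)] <- chance_level
  means <- sub |>
    dplyr::group_by(.data$sampling_interval) |>
    dplyr::summarise(mean_auc = mean(.data$guild_auc), .groups = "drop")
  list(best_interval = means$sampling_interval[which.max(means$mean_auc)],
       means = means)
}

#' Summarize an experiment table over realizations
#'
#' @param results Output of [run_guild_experiment()] or
#'   [sweep_sampling_intervals()].
#' @return A tibble of means and standard deviations per metric (and per
#'   sampling interval if present).
#' @export
summarize_experiment <- function(results) {
  groups <- intersect(c("sampling_interval", "metric"), names(results))
  results |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::summarise(dplyr::across(
      dplyr::any_of(c("spearman_rho", "link_auc", "guild_auc")),
      list(mean = ~mean(.x, na.rm = TRUE), sd = ~sd(.x, na.rm = TRUE))),
      n = dplyr::n(), .groups = "drop")
}
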