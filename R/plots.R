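# ggplot2 lives in Suggests: plotting is optional sugar over the tidy() output.

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_ecoguilds("install ggplot2 to use the plotting helpers")
}

#' Plot an ROC curve
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.roc_result <- function(object, ...) {
  need_ggplot()
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("%s detection, AUC = %.3f",
                                  object$task, object$auc))
}

#' Heatmap of a pairwise-metric matrix
#'
#' @param object A `metric_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.metric_matrix <- function(object, ...) {
  need_ggplot()
  n <- nrow(object)
  df <- tibble::tibble(i = rep(seq_len(n), n), j = rep(seq_len(n), each = n),
                       value = as.vector(unclass(object)))
  ggplot2::ggplot(df, ggplot2::aes(.data$j, .data$i, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = attr(object, "metric"))
}

#' Distance-binned metric means with the shuffle null
#'
#' @param object A `binned_association` (ideally from [index_shuffle_null()]).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.binned_association <- function(object, ...) {
  need_ggplot()
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$midpoint, .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Sequence distance", y = "Pairwise measure",
                  title = attr(object, "metric"))
  if ("null_mean" %in% names(df))
    p <- p + ggplot2::geom_pointrange(
      ggplot2::aes(y = .data$null_mean,
                   ymin = .data$null_mean - .data$null_sd,
                   ymax = .data$null_mean + .data$null_sd),
      colour = "grey55", alpha = 0.7)
  p
}

#' Sampling-interval sweep of guild-detection accuracy
#'
#' @param results Output of [sweep_sampling_intervals()].
#' @param measure Column to plot (default `"guild_auc"`).
#' @return A ggplot of mean +/- sd per metric and sampling interval.
#' @export
plot_sampling_sweep <- function(results, measure = "guild_auc") {
  need_ggplot()
  summ <- summarize_experiment(results)
  m <- paste0(measure, "_mean"); s <- paste0(measure, "_sd")
  ggplot2::ggplot(summ, ggplot2::aes(.data$sampling_interval, .data[[m]],
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data[[m]] - .data[[s]],
                                          ymax = .data[[m]] + .data[[s]])) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Sampling interval", y = measure)
}
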