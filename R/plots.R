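#' Plot grand-average ERPs by sequence type
#'
#' Grand averages (mean over participants) per group, task and sequence
#' type, the conventional disrupted-vs-intact overlay.
#'
#' @param erps an `spt_erp` table ([average_erp()]).
#' @param tasks optional subset of tasks.
#' @return a ggplot object.
#' @export
plot_erp <- function(erps, tasks = NULL) {
  dat <- erps
  if (!is.null(tasks)) dat <- filter(dat, .data$task %in% tasks)
  dat <- dat |>
    group_by(.data$group, .data$task, .data$sequence_type, .data$time) |>
    summarise(amplitude = mean(.data$amplitude), .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(.data$time, .data$amplitude,
                                    colour = .data$sequence_type)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(ggplot2::vars(.data$group),
                        ggplot2::vars(.data$task)) +
    ggplot2::labs(x = "time (ms)", y = "amplitude (µV)",
                  colour = "sequence") +
    ggplot2::theme_minimal()
}

#' t-series with significant clusters shaded
#'
#' @param object an `spt_cluster_test`.
#' @param alpha shading threshold for cluster significance.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot spt_cluster_test
#' @export
autoplot.spt_cluster_test <- function(object, alpha = 0.05, ...) {
  ts <- object$t_series
  crit <- object$settings$t_crit
  p <- ggplot2::ggplot(ts, ggplot2::aes(.data$time, .data$t)) +
    ggplot2::geom_hline(yintercept = c(-crit, crit), linetype = 2,
                        linewidth = 0.3) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "paired t") +
    ggplot2::theme_minimal()
  sig <- object$clusters[!is.na(object$clusters$p) &
                           object$clusters$p < alpha, ]
  if (nrow(sig)) {
    p <- p + ggplot2::geom_rect(
      data = sig, inherit.aes = FALSE, alpha = 0.2,
      ggplot2::aes(xmin = .data$start_ms, xmax = .data$end_ms,
                   ymin = -Inf, ymax = Inf))
  }
  p
}

#' Visuomotor learning curves (mean of per-participant median RTs)
#'
#' @param trials behavioural trial table.
#' @return a ggplot object: RT against stimulus position by group and
#'   sequence type.
#' @export
plot_learning_curves <- function(trials) {
  long <- visuomotor_long(trials)
  dat <- long |>
    group_by(.data$participant, .data$group, .data$sequence_type,
             .data$position) |>
    summarise(rt = median(.data$rt), .groups = "drop") |>
    group_by(.data$group, .data$sequence_type, .data$position) |>
    summarise(mean_rt = mean(.data$rt),
              se = sd(.data$rt) / sqrt(dplyr::n()), .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(.data$position, .data$mean_rt,
                                    colour = .data$group,
                                    linetype = .data$sequence_type)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_rt - .data$se,
                                          ymax = .data$mean_rt + .data$se),
                             size = 0.2) +
    ggplot2::scale_x_continuous(breaks = 1:12) +
    ggplot2::labs(x = "stimulus position", y = "reaction time (ms)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
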