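#' Plot a confidence-interval sweep
#'
#' Mean effect size with its percentile confidence ribbon against sampling
#' effort, faceted by depth when more than one depth was swept, with one
#' colour per test/metric combination — the standard presentation of
#' effort/depth precision trends.
#'
#' @param object A `ci_sweep` tibble from [run_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ci_sweep <- function(object, ...) {
  df <- dplyr::filter(object, .data$status == "ok")
  df$depth_label <- ifelse(is.na(df$depth), "no rarefaction",
                           paste0("depth ", df$depth))
  df$series <- paste(df$test, df$metric, sep = " / ")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$effort, y = .data$mean,
                                        colour = .data$series,
                                        fill = .data$series)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "samples per group (bootstrap effort)",
                  y = "effect size (mean of bootstrap replicates)",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
  if (length(unique(df$depth_label)) > 1) {
    p <- p + ggplot2::facet_wrap(~depth_label)
  }
  p
}

#' Plot a drift-detectability experiment
#'
#' ANOSIM R (and the p = 0.05 detection threshold) against sequencing depth
#' on a log axis, one line per number of samples per community.
#'
#' @param object A `drift_experiment` tibble from [drift_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.drift_experiment <- function(object, ...) {
  df <- object
  df$detected <- df$p_value < 0.05
  ggplot2::ggplot(df, ggplot2::aes(x = .data$depth, y = .data$statistic,
                                   colour = factor(.data$n_samples))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$detected), size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 16)) +
    ggplot2::labs(x = "sequencing depth (reads per sample)",
                  y = "ANOSIM R between drifted communities",
                  colour = "samples per\ncommunity",
                  shape = "p < 0.05") +
    ggplot2::theme_minimal()
}
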