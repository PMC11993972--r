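# Convenience ggplot2 charts for trajectories and grid summaries.

#' Plot the female-population trajectory of a run
#'
#' Adult wild females per week, with the burn-in shaded and the first release
#' marked.
#'
#' @param object A `medfly_sim`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.medfly_sim <- function(object, ...) {
  traj <- tidy(object)
  traj$t <- ifelse(traj$phase == "burn_in",
                   traj$week - object$config$burn_in_weeks, traj$week)
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$t, y = .data$wild_females)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = 0, ymin = -Inf, ymax = Inf,
                      alpha = 0.08) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "weeks since first release (burn-in shaded)",
      y = "adult wild females",
      title = sprintf("%s, release ratio %.2g every %d week(s)",
                      object$profile$name, object$schedule$release_ratio,
                      object$schedule$interval_weeks)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a grid summary
#'
#' Per-system curves of the mean elimination week (censored cells shown at the
#' horizon as open points) and of the mean female count over the last 20
#' release weeks, against release ratio or interval.
#'
#' @param object A `medfly_grid_summary` from [summarize_grid()].
#' @param x `"release_ratio"` or `"interval_weeks"`.
#' @param metric `"elimination"` or `"females"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.medfly_grid_summary <- function(object, x = c("release_ratio",
                                                       "interval_weeks"),
                                         metric = c("elimination", "females"),
                                         ...) {
  x <- match.arg(x)
  metric <- match.arg(metric)
  y <- if (metric == "elimination") "mean_elimination_week" else
    "mean_females_last20"
  ylab <- if (metric == "elimination") {
    "mean weeks to elimination (eliminating runs)"
  } else "mean adult females, last 20 release weeks"
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[x]], y = .data[[y]],
                                       colour = .data$system)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$censoring_fraction > 0.5)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                name = "mostly censored") +
    ggplot2::labs(x = gsub("_", " ", x), y = ylab) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
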