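# ggplot2 displays for PSTHs, group curves and plateau fits.

#' Plot a PSTH's instantaneous-frequency curve
#' @param object An `mua_psth`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mua_psth <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_mid, y = .data$rate_hz)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::annotate("rect", xmin = 0, xmax = 1.5, ymin = -Inf, ymax = Inf,
                      alpha = 0.08) +
    ggplot2::labs(x = "time after stimulus (s)",
                  y = "instantaneous frequency (Hz)",
                  title = sprintf("%s (%s)", object$slice_id, object$group)) +
    ggplot2::theme_minimal()
}

#' Plot group-aggregated evoked-response curves
#'
#' Mean +/- SEM across slices per group, per response window.
#'
#' @param agg Output of [aggregate_slices()].
#' @param what `"prob"` (relative probability) or `"freq"` (instantaneous
#'   frequency).
#' @return A ggplot.
#' @export
plot_group_curves <- function(agg, what = c("prob", "freq")) {
  what <- match.arg(what)
  if (what == "prob") {
    y <- "mean_prob"; s <- "sem_prob"; lab <- "relative probability"
  } else {
    y <- "mean_freq_hz"; s <- "sem_freq_hz"
    lab <- "instantaneous frequency (Hz)"
  }
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$t_mid, y = .data[[y]],
                                    color = .data$group,
                                    fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data[[y]] - .data[[s]],
                                      ymax = .data[[y]] + .data[[s]]),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~window, scales = "free_x") +
    ggplot2::labs(x = "time after stimulus (s)", y = lab) +
    ggplot2::theme_minimal()
}

#' Plot a fitted duration-probability curve
#' @param object A `plateau_fit`.
#' @param ... Unused.
#' @return A ggplot of the data points and the fitted plateau curve.
#' @export
autoplot.plateau_fit <- function(object, ...) {
  grid <- tibble(t = seq(0, max(object$data$t), length.out = 200))
  grid$y <- predict(object, grid)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$t, y = .data$y)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(data = grid, color = "firebrick") +
    ggplot2::labs(x = "episode duration (s)", y = "cumulative probability") +
    ggplot2::theme_minimal()
}
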