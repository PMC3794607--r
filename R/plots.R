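#' Plot replicate-mean expression time courses
#'
#' @param panel Long time-course tibble.
#' @param genes Optional character vector of genes to show (default: all).
#' @param log_y Plot expression on a log axis (default `TRUE`, the usual
#'   display for count-type expression data).
#' @return A ggplot object: one facet per gene, one line per strain.
#' @export
plot_timecourse <- function(panel, genes = NULL, log_y = TRUE) {
  traces <- mean_trace(panel)
  if (!is.null(genes)) traces <- filter(traces, .data$gene %in% genes)
  p <- ggplot2::ggplot(traces,
                       ggplot2::aes(x = .data$time_min, y = .data$value,
                                    colour = .data$strain)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~gene, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "expression")
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot a promoter-binding enrichment curve
#'
#' @param binding Binding curve tibble (`time_min`, `enrichment`).
#' @return A ggplot object with the no-binding baseline at 1 marked.
#' @export
plot_binding <- function(binding) {
  ggplot2::ggplot(binding,
                  ggplot2::aes(x = .data$time_min, y = .data$enrichment)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (min)", y = "fold enrichment")
}

#' Plot synthesis-rate residual traces
#'
#' @param residuals Output of [panel_residuals()] (or [residual_trace()] with a
#'   `gene` column added).
#' @param genes Optional subset of genes.
#' @return A ggplot object: residual vs time per gene, coloured by strain.
#' @export
plot_residuals <- function(residuals, genes = NULL) {
  if (!is.null(genes)) residuals <- filter(residuals, .data$gene %in% genes)
  ggplot2::ggplot(residuals,
                  ggplot2::aes(x = .data$time_min, y = .data$residual,
                               colour = .data$strain)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~gene) +
    ggplot2::labs(x = "time (min)", y = "synthesis-rate residual (1/min)")
}

#' @export
autoplot.decay_fit <- function(object, ...) {
  tt <- seq(0, max(object$data$time_min), length.out = 200)
  curve <- tibble(time_min = tt, value = exp(-object$k_deg * tt))
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$time_min, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "red") +
    ggplot2::labs(
      x = "time (min)", y = "abundance (t = 0 normalized)",
      title = sprintf("k_deg = %.4g /min, half-life %.3g min",
                      object$k_deg, object$half_life)
    )
}

#' @export
autoplot.ffl_fit <- function(object, ...) {
  model <- object$model
  model$k_y <- object$k_y
  model$beta_y <- object$k_y
  model$k_z <- object$k_z
  model$beta_z <- object$k_z
  sim <- simulate_ffl(model, object$x_input,
                      t_start = max(min(object$x_input$time_min), -10),
                      t_end = max(object$target$time_min))
  ggplot2::ggplot() +
    ggplot2::geom_line(
      data = sim,
      ggplot2::aes(x = .data$time_min, y = .data$z, colour = "model")
    ) +
    ggplot2::geom_point(
      data = object$target,
      ggplot2::aes(x = .data$time_min, y = .data$value, colour = "data")
    ) +
    ggplot2::scale_colour_manual(values = c(model = "grey40", data = "black"),
                                 name = NULL) +
    ggplot2::labs(x = "time (min)", y = "unit-scaled expression",
                  title = sprintf("FFL fit: k_Y = %.3g, k_Z = %.3g /min",
                                  object$k_y, object$k_z))
}
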