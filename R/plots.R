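#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_tile geom_ribbon
#'   facet_wrap labs scale_fill_gradient2 theme_minimal geom_col
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an action-potential trace
#'
#' Membrane voltage and intracellular calcium against time.
#'
#' @param object An `ap_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ap_trace <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("time_ms", "V_mV", "Ca_mM")],
    cols = c("V_mV", "Ca_mM"), names_to = "signal")
  ggplot(df, aes(x = .data$time_ms, y = .data$value)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~signal, ncol = 1, scales = "free_y") +
    labs(x = "time (ms)", y = NULL) +
    theme_minimal()
}

#' Heatmap of signed sensitivity indices
#'
#' @param object A combined sensitivity table with columns `input`,
#'   `output`, and the value column `value_col`.
#' @param value_col Column to display (default `"S_signed"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_sensitivity_heatmap <- function(object, value_col = "S_signed", ...) {
  ggplot(object, aes(x = .data$input, y = .data$output,
                     fill = .data[[value_col]])) +
    geom_tile() +
    scale_fill_gradient2(low = "steelblue", mid = "white",
                         high = "firebrick", midpoint = 0) +
    labs(x = NULL, y = NULL, fill = value_col) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}

#' @export
autoplot.sensitivity_result <- function(object, ...) {
  ggplot(object, aes(x = .data$input, y = .data$S_signed)) +
    geom_col() +
    labs(x = NULL, y = "signed first-order index") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}

#' Plot main-effect curves
#'
#' @param me Tibble from [main_effect()] (optionally with an `output`
#'   column for faceting).
#' @return A ggplot object.
#' @export
plot_main_effects <- function(me) {
  p <- ggplot(me, aes(x = .data$grid, y = .data$value,
                      color = .data$input)) +
    geom_line() +
    labs(x = "normalized input value", y = "expected output") +
    theme_minimal()
  if ("output" %in% names(me)) {
    p <- p + facet_wrap(~output, scales = "free_y")
  }
  p
}

#' Plot an APD restitution surface
#'
#' @param surf Tibble from [restitution_surface()].
#' @param second_input Name of the second swept column.
#' @return A ggplot object.
#' @export
plot_restitution_surface <- function(surf, second_input) {
  ggplot(surf, aes(x = .data$DI, y = .data$mean,
                   group = .data[[second_input]],
                   color = .data[[second_input]])) +
    geom_ribbon(aes(ymin = .data$lower, ymax = .data$upper,
                    fill = .data[[second_input]]),
                alpha = 0.15, color = NA) +
    geom_line() +
    labs(x = "normalized DI", y = "APD90 (ms)") +
    theme_minimal()
}
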