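#' Plot a normalized trace with detected events
#'
#' @param norm A `norm_trace`, or the long tibble from
#'   [normalize_traces()] (faceted by ROI).
#' @param events Optional event tibble; peaks are marked.
#' @return A ggplot.
#' @export
plot_trace <- function(norm, events = NULL) {
  d <- as_tibble(norm)
  if (!"roi" %in% names(d)) d$roi <- attr(norm, "roi") %||% "roi"
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~roi, ncol = 1) +
    ggplot2::labs(x = "time (s)", y = "normalized fluorescence") +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events)) {
    ev <- as_tibble(events)
    if (!"roi" %in% names(ev) || all(is.na(ev$roi))) ev$roi <- d$roi[1]
    p <- p + ggplot2::geom_point(
      data = ev,
      ggplot2::aes(x = .data$peak_time_s, y = .data$amplitude),
      colour = "red", shape = 17, size = 1.5
    )
  }
  p
}

#' Cumulative-probability plot of amplitude distributions
#'
#' @param cmp Result of [ecdf_compare()], or a tibble with `sample`,
#'   `value`, `cumprob` columns.
#' @return A ggplot of the two ECDFs.
#' @export
plot_ecdf <- function(cmp) {
  d <- if (is.list(cmp) && !is.data.frame(cmp)) cmp$ecdf else as_tibble(cmp)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value, y = .data$cumprob,
                                  colour = .data$sample)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "amplitude", y = "cumulative probability") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.match_result <- function(object, ...) {
  p <- object$pairs
  ggplot2::ggplot(p, ggplot2::aes(x = .data$amplitude_mv,
                                  y = .data$amplitude_optical)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "steelblue") +
    ggplot2::labs(
      x = "mEPSP amplitude (mV)", y = "optical amplitude (dF/F)",
      subtitle = sprintf("n = %d pairs; detection fraction %.2f; r = %.3f",
                         object$n_pairs, object$detection_fraction,
                         object$pearson_r)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
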