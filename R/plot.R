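#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point labs
#'   scale_x_reverse facet_wrap
#' @export
ggplot2::autoplot

#' Plot a profile
#'
#' Draws the statistic against the cutoff e with the x axis running from 0
#' (left) toward negative energies (right), the conventional orientation
#' for transition profiles.
#'
#' @param object a `pen_profile`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot pen_profile
#' @export
autoplot.pen_profile <- function(object, ...) {
  metric <- attr(object, "metric")
  ggplot(object, aes(x = .data$e, y = .data$value)) +
    geom_line() +
    geom_point(size = 0.8) +
    scale_x_reverse() +
    labs(x = "e (kJ/mol)", y = metric,
         title = sprintf("%s profile (%s channel)", metric, attr(object, "channel")))
}

#' @rdname autoplot.pen_profile
#' @method autoplot pen_comparison
#' @export
autoplot.pen_comparison <- function(object, ...) {
  d <- tidyr::pivot_longer(object$differences,
                           c("value_a", "value_b"),
                           names_to = "which", values_to = "value")
  d$protein <- ifelse(d$which == "value_a", object$labels[1], object$labels[2])
  ggplot(d, aes(x = .data$e, y = .data$value, colour = .data$protein)) +
    geom_line() +
    scale_x_reverse() +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "e (kJ/mol)", y = "value")
}

#' Plot several profiles together
#'
#' @param profiles named list of `pen_profile` objects sharing a grid.
#' @return a ggplot faceted by metric.
#' @export
plot_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  d <- dplyr::bind_rows(lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    tibble(metric = attr(p, "metric"), channel = attr(p, "channel"),
           e = p$e, value = p$value,
           series = names(profiles)[i] %||% as.character(i))
  }))
  ggplot(d, aes(x = .data$e, y = .data$value, colour = .data$series)) +
    geom_line() +
    scale_x_reverse() +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "e (kJ/mol)", y = "value")
}
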