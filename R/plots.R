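# ggplot2 graphics: reflectivity curves with model overlays, SLD and
# component volume-fraction profiles, and posterior traces.

#' Plot reflectivity data (and optionally a model)
#'
#' Log-log reflectivity vs Q with error bars, coloured by contrast and
#' faceted by dataset; a fitted model overlays as lines.
#'
#' @param data A [reflectivity_data()] tibble (any number of datasets).
#' @param fit Optional `nr_fit`; its model curves are drawn over the data.
#' @return A ggplot.
#' @export
plot_reflectivity <- function(data, fit = NULL) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$q, y = .data$r,
                                          colour = .data$contrast)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$r - .data$dr,
                                        ymax = .data$r + .data$dr),
                           alpha = 0.5, linewidth = 0.3) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$dataset)) +
    ggplot2::labs(x = expression(Q~group("[", ring(A)^-1, "]")),
                  y = "Reflectivity")
  if (!is.null(fit)) {
    m <- model_reflectivity(fit$problem)
    m <- dplyr::left_join(m, dplyr::distinct(data, .data$dataset,
                                             .data$contrast),
                          by = "dataset")
    p <- p + ggplot2::geom_line(data = m,
                                ggplot2::aes(y = .data$r_model),
                                linewidth = 0.4)
  }
  p
}

#' @describeIn plot_reflectivity autoplot method for component
#'   volume-fraction profiles (`nr_profile`): stacked per-component area
#'   curves against depth.
#' @param object An `nr_profile` from [component_profile()].
#' @param ... Unused.
#' @export
autoplot.nr_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"z",
                              names_to = "component",
                              values_to = "fraction")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$z, y = .data$fraction,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(z~group("[", ring(A), "]")),
                  y = "Volume fraction")
}

#' Plot an SLD depth profile
#'
#' @param profile Tibble with `z` and `sld` columns (see [sld_profile()]),
#'   optionally several stacked with a `contrast` column.
#' @return A ggplot.
#' @export
plot_sld_profile <- function(profile) {
  aes <- if ("contrast" %in% names(profile)) {
    ggplot2::aes(x = .data$z, y = .data$sld, colour = .data$contrast)
  } else {
    ggplot2::aes(x = .data$z, y = .data$sld)
  }
  ggplot2::ggplot(profile, aes) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(z~group("[", ring(A), "]")),
                  y = expression(SLD~group("[", 10^-6~ring(A)^-2, "]")))
}

#' @describeIn plot_reflectivity autoplot method for posteriors
#'   (`nr_posterior`): parameter trace plots with the burn-in shaded.
#' @export
autoplot.nr_posterior <- function(object, ...) {
  ch <- tibble::as_tibble(as.data.frame(object$chain))
  ch$step <- seq_len(nrow(ch))
  long <- tidyr::pivot_longer(ch, -"step", names_to = "term",
                              values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$value)) +
    ggplot2::annotate("rect", xmin = 0, xmax = object$burn_in,
                      ymin = -Inf, ymax = Inf, alpha = 0.15) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$term), scales = "free_y") +
    ggplot2::labs(x = "MCMC step", y = "Parameter value")
}
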