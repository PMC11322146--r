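# ggplot2 autoplot methods for the result objects

#' Plot a measurement series
#'
#' Faceted time series of the monitored quantities, gas phase (mol) and
#' aqueous phase (mol/kg) separately.
#'
#' @param object A [measurement_series()].
#' @param species Optional subset of species to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.measurement_series <- function(object, species = NULL, ...) {
  d <- tibble::as_tibble(object)
  if (!is.null(species)) d <- d[d$species %in% species, ]
  ggplot2::ggplot(d, ggplot2::aes(.data$day, .data$value,
                                  colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~phase, scales = "free_y") +
    ggplot2::labs(x = "day", y = "gas: mol / aqueous: mol per kg water",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot cumulative extents of reaction
#'
#' @param object A [compute_extents()] result.
#' @param ... Unused.
#' @return A ggplot of the cumulative extent of each metabolism with a
#'   3-sigma ribbon.
#' @export
autoplot.extent_trajectory <- function(object, ...) {
  d <- object$cumulative
  ggplot2::ggplot(d, ggplot2::aes(.data$day, .data$cum_extent,
                                  colour = .data$scheme,
                                  fill = .data$scheme)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = pmax(.data$cum_extent - 3 * .data$cum_sigma, 0),
      ymax = .data$cum_extent + 3 * .data$cum_sigma),
      alpha = 0.15, colour = NA) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "day", y = "cumulative extent (mol)",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the H2 budget
#'
#' Modeled total H2 (injected minus consumption attributed to the four
#' metabolisms) against the measured total where available.
#'
#' @param object An [h2_co2_budget()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.h2_budget <- function(object, ...) {
  d <- object$curves
  ggplot2::ggplot(d, ggplot2::aes(.data$day)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$h2_modeled,
                                    linetype = "modeled")) +
    ggplot2::geom_point(data = d[!is.na(d$h2_measured), ],
                        ggplot2::aes(y = .data$h2_measured,
                                     shape = "measured")) +
    ggplot2::labs(x = "day", y = "total H2 (mol)", linetype = NULL,
                  shape = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a speciation result
#'
#' Log-molality bars of the dissolved species.
#'
#' @param object A [speciate()] result.
#' @param min_molality Hide species below this molality.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.speciation <- function(object, min_molality = 1e-12, ...) {
  d <- object$species[object$species$molality > min_molality, ]
  d$species <- stats::reorder(d$species, -d$molality)
  ggplot2::ggplot(d, ggplot2::aes(.data$species, .data$molality)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "molality (mol/kg)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
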