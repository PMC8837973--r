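#' Plot tracer trajectories
#'
#' Line plot of simulated compartment amounts over time, faceted by organ.
#'
#' @param object A `tracer_trajectories` tibble from [simulate_tracer()].
#' @param species Optional character vector restricting plotted species.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tracer_trajectories <- function(object, species = NULL, ...) {
  d <- object
  if (!is.null(species)) {
    d <- filter(d, .data$species %in% !!species)
  }
  d <- filter(d, !.data$organ %in% c("sink", "peritoneum"))
  ggplot2::ggplot(d, ggplot2::aes(
    .data$time, .data$amount_nmol,
    colour = paste(.data$species, .data$label)
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~organ, scales = "free_y") +
    ggplot2::labs(
      x = "time after injection (h)", y = "amount (nmol)",
      colour = "species"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot pool-size kinetics
#'
#' Group mean +/- SE time courses of whole-compartment pools, faceted by
#' compartment, one line per analyte.
#'
#' @param pools Pool tibble with `time_point_h`, `matrix`, `analyte`,
#'   `amount_nmol`.
#' @param analytes Optional analyte filter.
#' @return A ggplot object.
#' @export
plot_pool_kinetics <- function(pools, analytes = NULL) {
  d <- as_tibble(pools)
  if (!is.null(analytes)) {
    d <- filter(d, .data$analyte %in% analytes)
  }
  summ <- d %>%
    group_by(.data$matrix, .data$analyte, .data$time_point_h) %>%
    summarise(
      mean = mean(.data$amount_nmol),
      se = sd(.data$amount_nmol) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(summ, ggplot2::aes(
    .data$time_point_h, .data$mean, colour = .data$analyte
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean - .data$se, ymax = .data$mean + .data$se
    ), size = 0.2) +
    ggplot2::facet_wrap(~matrix, scales = "free_y") +
    ggplot2::labs(
      x = "time after injection (h)", y = "pool size (nmol)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot methyl-corrected dose fractions over time
#'
#' @param fractions Output of [label_fraction_table()].
#' @return A ggplot object.
#' @export
plot_label_fractions <- function(fractions) {
  ggplot2::ggplot(fractions, ggplot2::aes(
    .data$time_h, .data$percent_of_dose, colour = .data$category
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$percent_of_dose - .data$se,
      ymax = .data$percent_of_dose + .data$se
    ), size = 0.2) +
    ggplot2::labs(
      x = "time after injection (h)",
      y = "% of administered D9-choline"
    ) +
    ggplot2::theme_minimal()
}
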