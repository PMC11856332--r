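#' Plot a trajectory
#'
#' Compartment counts over time, one line per class, faceted by host type.
#'
#' @param object A `sirs_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sirs_trajectory <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$year, y = .data$count,
                                     colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~host) +
    ggplot2::labs(x = "year", y = "individuals", colour = "class") +
    ggplot2::theme_minimal()
}

#' Plot a phase map
#'
#' Tiles over the (`mu`, `nu1`) plane coloured by the winning strain, with
#' cells where migrants outnumber residents marked by an asterisk.
#'
#' @param object A `sirs_phase_map` from [phase_map()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sirs_phase_map <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$winner_lab <- factor(ifelse(is.na(df$winner), "extinct",
                                 paste("strain", df$winner)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mu, y = .data$nu1,
                                        fill = .data$winner_lab)) +
    ggplot2::geom_tile(colour = "grey85") +
    ggplot2::labs(x = expression(mu ~ "(immunity loss rate)"),
                  y = expression(nu[1] ~ "(Habitat 1 recovery rate)"),
                  fill = "winner") +
    ggplot2::theme_minimal()
  dom <- df[df$migrants_dominate, , drop = FALSE]
  if (nrow(dom) > 0)
    p <- p + ggplot2::geom_point(data = dom, shape = 8, size = 2,
                                 colour = "black",
                                 ggplot2::aes(x = .data$mu, y = .data$nu1),
                                 inherit.aes = FALSE)
  p
}

#' Plot transition boundaries
#'
#' The recovery-rate thresholds at which the winner switches 1 to 2 and 2 to
#' 3, as functions of `mu`, coloured by `delta_I` when several curves are
#' combined (e.g. via `dplyr::bind_rows`).
#'
#' @param object A `sirs_transition_curve` from [transition_boundaries()],
#'   or several row-bound together.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sirs_transition_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("nu1_1to2", "nu1_2to3"),
                              names_to = "transition", values_to = "nu1")
  long$transition <- ifelse(long$transition == "nu1_1to2",
                            "strain 1 to 2", "strain 2 to 3")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mu, y = .data$nu1,
                                     colour = factor(.data$delta_I))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~transition) +
    ggplot2::labs(x = expression(mu), y = expression(nu[1]),
                  colour = expression(delta[I])) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
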