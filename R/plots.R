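#' Plot an ODE trajectory
#'
#' Concentration-versus-time curves, one line per species.
#'
#' @param object an `ode_trajectory` from [simulate_ode()].
#' @param species optional subset of species to show.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ode_trajectory <- function(object, species = NULL, ...) {
  df <- object
  if (!is.null(species)) df <- dplyr::filter(df, .data$species %in% !!species)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$concentration,
                                   colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (time units)", y = "concentration (mM/L)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a trajectory or cycle through the state graph
#'
#' Betweenness along the walk, with each state coloured by its fate
#' classification (toward the deadlock, toward recovery, or a bifurcation
#' from which both remain reachable).
#'
#' @param object a `brn_trajectory`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.brn_trajectory <- function(object, ...) {
  df <- object$states
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$betweenness)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$classification),
                        size = 2.5) +
    ggplot2::scale_x_continuous(breaks = df$step, labels = df$state) +
    ggplot2::labs(x = NULL, y = "betweenness centrality", colour = NULL,
                  title = sprintf("%s (mean betweenness %.2f)", object$kind,
                                  object$mean_betweenness)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Heatmap of a parameter-set catalog
#'
#' One column per catalog member, one row per logical parameter, tiles
#' coloured by the K value — the compact way to compare the identified
#' parameter sets.
#'
#' @param object a `brn_catalog`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.brn_catalog <- function(object, ...) {
  tab <- parameter_table(object)
  tab$param <- paste0(tab$entity, "(", tab$resources, ")")
  long <- tidyr::pivot_longer(tab, dplyr::all_of(object$labels),
                              names_to = "model", values_to = "K")
  long$model <- factor(long$model, levels = object$labels)
  long$param <- factor(long$param, levels = rev(unique(tab$param)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$model, y = .data$param,
                                     fill = factor(.data$K))) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::labs(x = NULL, y = NULL, fill = "K") +
    ggplot2::theme_minimal()
}

#' Betweenness profile of a state graph
#'
#' Ranked betweenness of all states (log-friendly overview of the
#' centrality structure), highlighting any states supplied.
#'
#' @param object a `state_graph`.
#' @param highlight optional digit-string states to mark.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.state_graph <- function(object, highlight = NULL, ...) {
  cmap <- state_betweenness(object)
  cmap$highlighted <- cmap$state %in% (highlight %||% character())
  p <- ggplot2::ggplot(cmap, ggplot2::aes(x = .data$rank,
                                          y = .data$betweenness)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$highlighted),
                        show.legend = any(cmap$highlighted)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "rank", y = "betweenness centrality",
                  colour = "highlighted") +
    ggplot2::theme_minimal()
  p
}
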