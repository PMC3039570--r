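#' Plot methods for result objects
#'
#' `autoplot()` methods returning ggplot objects: the NScore landscape of
#' a flux result (observed NScores with the significance cutoff), and the
#' binned positional profile of protein sets along pathways.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot.
#' @name plots
NULL

#' @rdname plots
#' @export
autoplot.flux_result <- function(object, ...) {
  d <- tibble::as_tibble(object) |> dplyr::filter(!is.na(.data$nscore))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$nscore, fill = .data$significant)) +
    ggplot2::geom_histogram(bins = 40, alpha = 0.85) +
    ggplot2::geom_vline(xintercept = attr(object, "cutoff"),
                        linetype = "dashed") +
    ggplot2::labs(x = "NScore", y = "term pairs",
                  title = sprintf("%d of %d BP-pair fluxes significant at %g%%",
                                  sum(d$significant), nrow(d),
                                  100 * attr(object, "alpha"))) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
autoplot.positional_profile <- function(object, ...) {
  h <- object$histogram |>
    dplyr::group_by(.data$set) |>
    dplyr::mutate(frac = .data$n / pmax(1, sum(.data$n))) |>
    dplyr::ungroup()
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin, y = .data$frac,
                                  fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "relative pathway position (0 = source, 1 = end)",
                  y = "fraction of set") +
    ggplot2::theme_minimal()
}

#' Degree distribution on log-log axes with the fitted power-law slope
#'
#' @param graph igraph object.
#' @return A ggplot of the degree histogram on log10 axes with the OLS
#'   power-law fit from [powerlaw_exponent()] in the subtitle.
#' @export
plot_degree_distribution <- function(graph) {
  deg <- igraph::degree(graph)
  tab <- table(deg[deg > 0])
  d <- tibble::tibble(degree = as.numeric(names(tab)),
                      frequency = as.numeric(tab))
  slope <- powerlaw_exponent(deg)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$degree, y = .data$frequency)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(title = "degree distribution",
                  subtitle = sprintf("power-law exponent (OLS) %.2f", slope)) +
    ggplot2::theme_minimal()
}

#' Shortest-path distance distributions for labelled node-set pairs
#'
#' @param graph igraph object.
#' @param sets Named list of character vectors of node names; every
#'   unordered combination of sets (including each set with itself) is
#'   profiled.
#' @return A ggplot of the distance distributions.
#' @export
plot_shortest_path_distributions <- function(graph, sets) {
  combos <- expand.grid(a = names(sets), b = names(sets),
                        stringsAsFactors = FALSE)
  combos <- combos[combos$a <= combos$b, ]
  d <- purrr::pmap(combos, function(a, b) {
    h <- shortest_path_distribution(graph, sets[[a]], sets[[b]])
    h |> dplyr::mutate(pair = paste(a, b, sep = " - "),
                       frac = .data$n / sum(.data$n))
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(d, ggplot2::aes(x = .data$distance, y = .data$frac,
                                  colour = .data$pair)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "shortest-path distance", y = "fraction of pairs") +
    ggplot2::theme_minimal()
}
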