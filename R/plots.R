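#' Stacked-bar plot of direct nutrient contributions
#'
#' Displays the output of [tca_contribution_pipeline()] as stacked bars of
#' direct contributions per tissue, faceted by target metabolite and diet,
#' the standard presentation for cross-tracer contribution analyses.
#'
#' @param contributions Tibble from [tca_contribution_pipeline()].
#' @return A ggplot object.
#' @export
plot_contributions <- function(contributions) {
  ggplot2::ggplot(contributions,
                  ggplot2::aes(x = .data$tissue, y = .data$contribution,
                               fill = .data$nutrient)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$target),
                        cols = ggplot2::vars(.data$diet)) +
    ggplot2::labs(x = NULL, y = "Direct contribution",
                  fill = "Circulating nutrient") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Truth-versus-estimate recovery scatter
#'
#' Plots estimates from [recover_experiment()] against their ground-truth
#' values, one panel per quantity, with the identity line; points on the
#' line are perfectly recovered.
#'
#' @param recovery Tibble from [recover_experiment()].
#' @return A ggplot object.
#' @export
plot_recovery <- function(recovery) {
  ggplot2::ggplot(recovery,
                  ggplot2::aes(x = .data$truth, y = .data$estimate,
                               colour = .data$diet)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$quantity), scales = "free") +
    ggplot2::labs(x = "Ground truth", y = "Estimate", colour = "Diet") +
    ggplot2::theme_minimal()
}

#' Bar plot of a single direct-contribution fit
#'
#' @param object A `direct_contrib` object from [direct_contributions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.direct_contrib <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$nutrient,
                                   y = .data$contribution)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Direct contribution") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
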