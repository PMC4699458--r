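#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_point geom_abline
#'   geom_errorbar geom_smooth labs scale_fill_manual theme_minimal theme
#'   element_text
#' @export
ggplot2::autoplot

#' Plot a missingness map
#'
#' Subject-visit by variable tile map, observed vs missing -- the standard
#' visual for panel-structured missingness.
#'
#' @param object A `missingness_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.missingness_map <- function(object, ...) {
  d <- tibble::as_tibble(object$matrix, rownames = "record") |>
    tidyr::pivot_longer(-"record", names_to = "variable",
                        values_to = "missing")
  ggplot(d, aes(x = .data$variable, y = .data$record,
                fill = .data$missing)) +
    geom_tile() +
    scale_fill_manual(values = c(`FALSE` = "grey85", `TRUE` = "grey20"),
                      labels = c("observed", "missing"), name = NULL) +
    labs(x = NULL, y = NULL, title = "Missingness map") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 60, hjust = 1),
          axis.text.y = element_text(size = 4))
}

#' Plot an overimputation diagnostic
#'
#' Observed values against their re-imputed means with 90% intervals; under a
#' well-specified imputation model about 90% of intervals cross the y = x
#' line.
#'
#' @param object An `overimputation` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.overimputation <- function(object, ...) {
  ggplot(object$cells, aes(x = .data$observed, y = .data$mean_imputation)) +
    geom_errorbar(aes(ymin = .data$lower, ymax = .data$upper,
                      colour = .data$covered), width = 0) +
    geom_point(size = 0.8) +
    geom_abline(slope = 1, intercept = 0, linetype = 2) +
    labs(title = paste0("Overimputation: ", object$variable),
         subtitle = sprintf("coverage of 90%% intervals: %.0f%%",
                            100 * object$coverage),
         x = "observed", y = "mean imputation") +
    theme_minimal()
}

#' Plot a concordance regression
#'
#' Scatter of the two estimate vectors with the fitted least-squares line and
#' the identity line.
#'
#' @param object A `concordance` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.concordance <- function(object, ...) {
  pts <- attr(object, "points")
  ggplot(pts, aes(x = .data$a, y = .data$b)) +
    geom_point() +
    geom_abline(slope = 1, intercept = 0, linetype = 3) +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                linewidth = 0.5, colour = "steelblue") +
    labs(x = "estimates A", y = "estimates B",
         subtitle = sprintf("slope %.3f, R² %.3f, p %.2g",
                            object$slope, object$r_squared, object$p_value)) +
    theme_minimal()
}
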