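#' Plot a fitted height-diameter curve over the data
#'
#' @param object An `hd_fit`.
#' @param ... Unused.
#' @return A ggplot: height against DBH with the fitted curve.
#' @exportS3Method ggplot2::autoplot
autoplot.hd_fit <- function(object, ...) {
  if (!object$converged) abort("Cannot plot a non-converged fit.")
  grid <- tibble(dbh = seq(min(object$data$dbh), max(object$data$dbh),
                           length.out = 200))
  grid$height <- predict_height(object, grid$dbh)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$dbh, y = .data$height)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_line(data = grid, colour = "#D55E00", linewidth = 1) +
    ggplot2::labs(x = "DBH (cm)", y = "Total height (m)",
                  title = sprintf("%s fit (RSE %.2f m)", object$spec$name,
                                  object$rse))
}

#' Compare several fitted height-diameter curves
#'
#' @param data Inventory tibble with `dbh` and `height`.
#' @param fits Tibble from [fit_hd_models()] or [rank_hd_models()].
#' @param n_best Number of top-ranked models to draw.
#' @return A ggplot overlaying the best model curves on the data.
#' @export
plot_hd_fits <- function(data, fits, n_best = 3) {
  ranked <- if ("rank" %in% names(fits)) fits else rank_hd_models(fits)
  ranked <- ranked[ranked$converged, ]
  take <- head(seq_len(nrow(ranked)), n_best)
  grid <- purrr::map_dfr(take, function(i) {
    fit <- ranked$fit[[i]]
    g <- tibble(dbh = seq(min(data$dbh, na.rm = TRUE),
                          max(data$dbh, na.rm = TRUE), length.out = 200))
    g$height <- predict_height(fit, g$dbh)
    g$model <- fit$spec$name
    g
  })
  ggplot2::ggplot(data, ggplot2::aes(x = .data$dbh, y = .data$height)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.8, colour = "grey40") +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(colour = .data$model), linewidth = 1) +
    ggplot2::labs(x = "DBH (cm)", y = "Total height (m)", colour = "Model")
}

#' Plot stratified error summaries
#'
#' @param errors Tibble from [compare_height_models()] or
#'   [biomass_error_comparison()].
#' @param metric Which proportional metric to draw.
#' @return A ggplot of the metric (in %) by size class and model/comparator.
#' @export
plot_error_summary <- function(errors, metric = c("cvse", "cvte", "cvre")) {
  metric <- match.arg(metric)
  group <- if ("model" %in% names(errors)) "model" else "comparator"
  ggplot2::ggplot(errors,
                  ggplot2::aes(x = .data$size_class,
                               y = 100 * .data[[metric]],
                               fill = .data[[group]])) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "DBH size class (cm)", y = paste0(toupper(metric), " (%)"),
                  fill = NULL)
}

#' Plot cumulative biomass curves by height source
#'
#' @param cumulative Tibble from [run_compare()]'s `cumulative` element (a
#'   [cumulative_biomass()] table with a `height_source` column).
#' @return A ggplot of cumulative Mg per ha against the DBH class upper bound.
#' @export
plot_cumulative_biomass <- function(cumulative) {
  ggplot2::ggplot(cumulative,
                  ggplot2::aes(x = .data$dbh_class_upper,
                               y = .data$agb_cum_mg_ha,
                               colour = .data$height_source)) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = "DBH class upper bound (cm)",
                  y = expression("Cumulative AGB (Mg ha"^-1*")"),
                  colour = "Height source")
}
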