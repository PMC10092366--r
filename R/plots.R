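#' Coefficient plot for a fitted trend model
#'
#' Fixed-effect estimates with 95% Wald intervals; significant terms
#' highlighted.
#'
#' @param object a `trend_fit`.
#' @param alpha significance level for highlighting.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.trend_fit <- function(object, alpha = 0.05, ...) {
  d <- dplyr::filter(object$wald, .data$term != "(Intercept)",
                     !is.na(.data$estimate))
  d$significant <- d$p_value < alpha
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$estimate, y = stats::reorder(.data$term, .data$estimate),
    colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - qnorm(1 - alpha / 2) * .data$std_error,
      xmax = .data$estimate + qnorm(1 - alpha / 2) * .data$std_error)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#B2182B",
                                            `FALSE` = "grey40")) +
    ggplot2::labs(x = "estimate (95% Wald interval)", y = NULL,
                  colour = sprintf("p < %.2g", alpha)) +
    ggplot2::theme_minimal()
}

#' Biplot-style view of the fast-slow axis
#'
#' Species scores on the first two axes with trait loadings overlaid;
#' PC1 runs from slow (left) to fast (right) species.
#'
#' @param object a `life_history_pca`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.life_history_pca <- function(object, ...) {
  sc <- object$scores
  ld <- tibble::as_tibble(object$loadings, rownames = "trait")
  scale_arrow <- 0.8 * max(abs(c(sc$pc1, sc$pc2))) /
    max(abs(ld[, c("PC1", "PC2")]))
  ggplot2::ggplot(sc, ggplot2::aes(.data$pc1, .data$pc2)) +
    ggplot2::geom_point(alpha = 0.5, colour = "grey30") +
    ggplot2::geom_segment(
      data = ld,
      ggplot2::aes(x = 0, y = 0, xend = .data$PC1 * scale_arrow,
                   yend = .data$PC2 * scale_arrow),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "#2166AC") +
    ggplot2::geom_text(
      data = ld,
      ggplot2::aes(x = .data$PC1 * scale_arrow * 1.1,
                   y = .data$PC2 * scale_arrow * 1.1,
                   label = .data$trait),
      colour = "#2166AC", size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (fast-slow continuum, %.0f%%)",
                  100 * object$variance_explained[1]),
      y = sprintf("PC2 (%.0f%%)", 100 * object$variance_explained[2])) +
    ggplot2::theme_minimal()
}

#' Plot population time series with imputed values marked
#'
#' @param imputed imputation table from [impute_populations()].
#' @param ids population ids to draw (default: first 12).
#' @return a ggplot (log10 abundance vs year, imputed points hollow).
#' @export
plot_population_series <- function(imputed, ids = NULL) {
  ids <- ids %||% head(unique(imputed$population_id), 12L)
  d <- dplyr::filter(imputed, .data$population_id %in% ids)
  ggplot2::ggplot(d, ggplot2::aes(.data$year, .data$abundance)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$imputed), size = 1.8) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1)) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~population_id, scales = "free_y") +
    ggplot2::labs(y = "abundance (log scale)", shape = "imputed") +
    ggplot2::theme_minimal()
}
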