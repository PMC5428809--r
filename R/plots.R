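# ggplot2 visualisations of the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted psychometric function
#'
#' Observed '+' proportions per level with the fitted logit curve; the
#' dashed verticals mark the PSE and the 25/75% points whose half
#' distance, normalized by the PSE, is the Weber ratio.
#'
#' @param object A converged [fit_logit()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.psychometric_fit <- function(object, ...) {
  obs <- tibble::tibble(level = object$levels,
                        prop = object$plus_counts / object$n_per_level)
  grid <- tibble::tibble(
    level = seq(min(object$levels), max(object$levels), length.out = 200))
  grid$p <- stats::plogis((grid$level - object$mu) / object$s)
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$level, y = .data$prop)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$p),
                       colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = object$pse, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::labs(x = "magnitude", y = "proportion '+'",
                  subtitle = sprintf("PSE = %.3g, WR = %.3g",
                                     object$pse, object$wr)) +
    ggplot2::theme_minimal()
}

#' Plot a central-tendency regression
#'
#' @param object A [fit_tendency()] object.
#' @param ... Unused.
#' @return A ggplot (fitted line against the identity diagonal; a
#'   shallower-than-identity line is the central-tendency signature).
#' @export
autoplot.tendency_fit <- function(object, ...) {
  grid <- tibble::tibble(x = c(0, 100))
  grid$y <- object$intercept + object$slope * grid$x
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line(colour = "steelblue", linewidth = 1) +
    ggplot2::coord_equal(xlim = c(0, 100), ylim = c(0, 100)) +
    ggplot2::labs(x = "magnitude (%)", y = "estimate (%)",
                  subtitle = sprintf("slope = %.2f, intercept = %.1f",
                                     object$slope, object$intercept)) +
    ggplot2::theme_minimal()
}

#' Heatmap of a slope correlation matrix
#'
#' Cells surviving the Bonferroni correction are outlined.
#'
#' @param object A [correlation_matrix()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.slope_correlations <- function(object, ...) {
  df <- as.data.frame(as.table(object$r))
  names(df) <- c("row", "col", "r")
  sig <- as.data.frame(as.table(object$significant))
  df$significant <- sig$Freq
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = df[df$significant, ], fill = NA,
                       colour = "black", linewidth = 0.8) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "steelblue",
                                  high = "firebrick", mid = "white") +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Raster plot of a realized stimulus
#'
#' Dots drawn at their positions with their sizes; colour codes onset
#' time, so the accumulation regime is visible at a glance.
#'
#' @param object A [realize_stimulus()] result with placed dots.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stimulus <- function(object, ...) {
  ev <- object$events
  if (!"x_deg" %in% names(ev)) {
    stop_dotmag("stimulus was realized without placement; re-run with place = TRUE")
  }
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$x_deg, y = .data$y_deg,
                                   size = .data$diameter_deg,
                                   colour = .data$onset_ms)) +
    ggplot2::geom_point() +
    ggplot2::scale_size_identity() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (deg)", y = "y (deg)", colour = "onset (ms)") +
    ggplot2::theme_minimal()
}
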