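#' Plot a feature-occurrence histogram
#'
#' Bar chart of occurrence counts across SFS repetitions, ranked; the top
#' two features (first and second place) are highlighted and the final
#' selected subset annotated.
#'
#' @param object An `ehg_selection`.
#' @param top_n Show only the `top_n` highest bars (default all).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ehg_selection <- function(object, top_n = NULL, ...) {
  h <- object$histogram
  if (!is.null(top_n)) h <- head(h, top_n)
  h$feature <- factor(h$feature, levels = rev(h$feature))
  h$top2 <- seq_len(nrow(h)) <= 2L
  h$final <- h$feature %in% object$final_subset
  ggplot2::ggplot(h, ggplot2::aes(x = .data$count, y = .data$feature,
                                  fill = .data$top2)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "black",
                                          `FALSE` = "grey60")) +
    ggplot2::labs(
      x = sprintf("occurrences in %d SFS repetitions", object$n_reps),
      y = NULL,
      title = sprintf("Feature occurrences (%s), final subset m = %d",
                      object$kind, object$m_final)) +
    ggplot2::theme_minimal()
}

#' Plot an averaged ROC curve
#'
#' @param object An `ehg_avg_roc`.
#' @param ... Unused.
#' @return A ggplot object with the mean curve and an SD ribbon.
#' @export
autoplot.ehg_avg_roc <- function(object, ...) {
  p <- object$points
  ggplot2::ggplot(p, ggplot2::aes(.data$fpr, .data$mean_tpr)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = pmax(.data$mean_tpr - .data$sd_tpr, 0),
      ymax = pmin(.data$mean_tpr + .data$sd_tpr, 1)), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey50") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate (1 - Sp)",
                  y = "sensitivity (Se)") +
    ggplot2::theme_minimal()
}

#' Scatter plot of the two-feature space with decision boundaries
#'
#' @param table Feature table.
#' @param features Two feature column names (x then y).
#' @param boundaries Optional list of `ehg_boundary` objects to overlay
#'   (1-D thresholds as a vertical line, 2-D isolines as contours).
#' @return A ggplot object.
#' @export
plot_feature_space <- function(table, features, boundaries = list()) {
  stopifnot(length(features) == 2L)
  p <- ggplot2::ggplot(table, ggplot2::aes(
    x = .data[[features[1]]], y = .data[[features[2]]],
    colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(premature = "firebrick",
                                            term = "forestgreen")) +
    ggplot2::theme_minimal()
  for (b in boundaries) {
    if (b$mode == "threshold_1d") {
      p <- p + ggplot2::geom_vline(xintercept = b$threshold,
                                   colour = "brown")
    } else {
      for (seg in b$contour) {
        p <- p + ggplot2::annotate("path", x = seg$x, y = seg$y,
                                   colour = "blue")
      }
    }
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
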