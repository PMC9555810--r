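#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Better-Worse quadrant plot
#'
#' Scatter of attributes at (Worse, Better) with quadrant reference lines
#' at the threshold. Points are coloured by quadrant and labelled by
#' attribute id.
#'
#' @param x A metrics tibble, a `kano_analysis` object, or a points tibble
#'   from [better_worse_points()].
#' @param threshold Quadrant threshold in (0, 100).
#' @param label Draw attribute-id labels next to the points.
#' @return A ggplot object.
#' @examples
#' plot_better_worse(kano_metrics(telenursing_counts()))
#' @export
plot_better_worse <- function(x, threshold = 50, label = TRUE) {
  pts <- if (is.data.frame(x) && all(c("quadrant", "worse", "better") %in% names(x))) {
    x
  } else {
    better_worse_points(x, threshold)
  }
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$worse, y = .data$better)) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$quadrant), size = 2.5) +
    ggplot2::scale_x_continuous(limits = c(0, 100)) +
    ggplot2::scale_y_continuous(limits = c(0, 100)) +
    ggplot2::labs(
      x = "Worse (dissatisfaction coefficient, %)",
      y = "Better (satisfaction coefficient, %)",
      colour = "Quadrant"
    ) +
    ggplot2::theme_minimal()
  if (label) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data$attribute_id),
      nudge_x = 2.2, nudge_y = 1.5, size = 3
    )
  }
  p
}

#' @describeIn plot_better_worse autoplot method for `kano_analysis`.
#' @param object A `kano_analysis` object.
#' @param ... Passed to [plot_better_worse()].
#' @export
autoplot.kano_analysis <- function(object, ...) {
  plot_better_worse(object, ...)
}

#' Plot per-attribute p-values of a group comparison
#'
#' Dot plot of the rank-sum p-value per attribute with a reference line at
#' the significance level.
#'
#' @param object A `kano_comparison` object.
#' @param alpha Reference significance level.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kano_comparison <- function(object, alpha = 0.05, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = factor(.data$attribute_id), y = .data$p)) +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dashed", colour = "red") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Attribute", y = "Rank-sum p-value",
      title = paste0("Group comparison by ", attr(object, "group_name"))
    ) +
    ggplot2::theme_minimal()
}
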