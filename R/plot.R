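#' Plot boundary scores along a read
#'
#' Line plot of the B (repeat start) and E (repeat end) statistics from
#' [boundary_scores()]; peaks mark putative repeat boundaries.
#'
#' @param scores Tibble from [boundary_scores()].
#' @param theta_b Optional acceptance floor drawn as a reference line.
#' @return A ggplot object.
#' @export
plot_boundary_scores <- function(scores, theta_b = NULL) {
  p <- ggplot2::ggplot(scores,
                       ggplot2::aes(x = .data$pos, y = .data$score)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~stat, ncol = 1) +
    ggplot2::labs(x = "read position (nt)", y = "boundary score")
  if (!is.null(theta_b)) {
    p <- p + ggplot2::geom_hline(yintercept = theta_b, linetype = 2,
                                 colour = "red")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Sensitivity plot of a synthetic benchmark
#'
#' Sensitivity as a function of unit length, one line per copy number -
#' the standard way benchmark sweeps of this kind are displayed.
#'
#' @param object A `"tandem_benchmark"` from [run_benchmark()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot tandem_benchmark
#' @export
autoplot.tandem_benchmark <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$unit_len),
                               y = .data$sensitivity,
                               colour = factor(.data$copies),
                               group = factor(.data$copies))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "unit length (nt)", y = "sensitivity",
                  colour = "copies")
}
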