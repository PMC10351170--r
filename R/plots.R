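# ggplot2 views of safety-window results.

#' Plot safety windows along both sequences
#'
#' Draws the representative (A) and member (B) sequences as horizontal
#' tracks with the window projections as colored segments; window
#' proportions map to color.
#'
#' @param windows a windows tibble with projection columns (`a_start`,
#'   `a_end`, `b_start`, `b_end`, `proportion`).
#' @param n,m sequence lengths of A and B.
#' @param a_name,b_name track labels.
#' @return a ggplot object.
#' @export
plot_safety_windows <- function(windows, n, m, a_name = "A (representative)",
                                b_name = "B (member)") {
  segs <- dplyr::bind_rows(
    tibble::tibble(seq = a_name, start = windows$a_start,
                   end = windows$a_end, proportion = windows$proportion),
    tibble::tibble(seq = b_name, start = windows$b_start,
                   end = windows$b_end, proportion = windows$proportion))
  segs <- segs[segs$end > segs$start, ]
  backbone <- tibble::tibble(seq = c(a_name, b_name), start = 0,
                             end = c(n, m))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = backbone,
      ggplot2::aes(x = .data$start, xend = .data$end, y = .data$seq,
                   yend = .data$seq),
      linewidth = 0.4, color = "grey60") +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$start, xend = .data$end, y = .data$seq,
                   yend = .data$seq, color = .data$proportion),
      linewidth = 4, lineend = "butt") +
    ggplot2::scale_color_viridis_c(limits = c(0, 1), name = "p(window)") +
    ggplot2::labs(x = "residue position (0-based)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_safety_windows
#' @param object a [align_safety()] fit.
#' @param ... unused.
#' @export
autoplot.safety_alignment <- function(object, ...) {
  plot_safety_windows(object$windows, object$n, object$m) +
    ggplot2::ggtitle(sprintf("alpha = %g, delta = %g: %d safety windows",
                             object$alpha, object$delta,
                             nrow(object$windows)))
}
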