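#' Plot methods
#'
#' ggplot2 `autoplot()` methods for the package's result types: the
#' normalized coverage track (log2 coverage along the chromosome, with
#' detected boundaries if supplied), the bin-pair matrices (grayscale
#' heatmap, white low and black high), the enrichment profile, and a
#' volcano-style view of a differential-expression result.
#'
#' @param object The object to plot.
#' @param rc Optional `rc_result` whose boundaries are drawn as dashed lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @name oriterscan-plots
NULL

#' @rdname oriterscan-plots
#' @method autoplot norm_coverage
#' @export
autoplot.norm_coverage <- function(object, rc = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$start, y = .data$log2)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4) +
    ggplot2::labs(x = "chromosome position (bp)",
                  y = "log2 coverage (mode-normalized)") +
    ggplot2::theme_minimal()
  if (!is.null(rc)) {
    p <- p + ggplot2::geom_vline(xintercept = c(rc$boundary_1, rc$boundary_2),
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' @rdname oriterscan-plots
#' @param which `"anticorrelated"` (default, matching the domain heatmap) or
#'   `"correlated"`.
#' @method autoplot binpair_matrix
#' @export
autoplot.binpair_matrix <- function(object, which = c("anticorrelated", "correlated"),
                                    ...) {
  which <- match.arg(which)
  df <- tidy.binpair_matrix(object)
  df$value <- df[[which]]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_a, y = .data$bin_b,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "black") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "chromosome bin", y = "chromosome bin",
                  fill = paste0(which, "\npairs")) +
    ggplot2::theme_minimal()
}

#' @rdname oriterscan-plots
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$start, y = .data$observed - .data$null_mean,
                               colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~window_size, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "window start (bp)", y = "observed - null mean") +
    ggplot2::theme_minimal()
}

#' @rdname oriterscan-plots
#' @method autoplot de_result
#' @export
autoplot.de_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$mlp <- -log10(pmax(df$p_value, 1e-300))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fc, y = .data$mlp,
                                   colour = .data$call)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(up = "firebrick", down = "steelblue",
                                            ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 P") +
    ggplot2::theme_minimal()
}
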