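# ggplot2 views of the main result types

#' Plot methods
#'
#' `autoplot()` methods give quick diagnostic views: a Manhattan-style
#' track of standardized scores for a `sweep_scan`, the windowed mean-|z|
#' track with called peaks shaded for `sweep_windows`, and proportion
#' bars with Fisher p labels for an `impact_enrichment` table.
#' `plot_upset_counts()` shows the structural-variant set sizes with
#' their assembly presence patterns.
#'
#' @param object The object to plot.
#' @param peaks Optional `sweep_peaks` tibble to shade on a windows plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name plots
NULL

#' @rdname plots
#' @export
autoplot.sweep_scan <- function(object, ...) {
  d <- object[object$valid & !is.na(object$z), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos / 1e6,
                                  y = .data$z)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.6) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)",
                  y = sprintf("standardized %s", toupper(d$metric[1]))) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
autoplot.sweep_windows <- function(object, peaks = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = (.data$first_pos + .data$last_pos) / 2e6,
                                    y = abs(.data$mean_z))) +
    ggplot2::geom_hline(yintercept = c(0.5, 1.5), linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "window midpoint (Mb)", y = "|mean z|") +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks) > 0) {
    p <- p + ggplot2::geom_rect(
      data = peaks,
      ggplot2::aes(xmin = .data$start_pos / 1e6, xmax = .data$end_pos / 1e6,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "firebrick", alpha = 0.15)
  }
  p
}

#' @rdname plots
#' @export
autoplot.impact_enrichment <- function(object, ...) {
  d <- tidyr::pivot_longer(object, c("prop_in", "prop_out"),
                           names_to = "where", values_to = "prop")
  d$where <- ifelse(d$where == "prop_in", "sweep regions", "genome-wide")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$impact, y = .data$prop,
                                  fill = .data$where)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_text(
      data = object,
      ggplot2::aes(x = .data$impact, y = pmax(.data$prop_in, .data$prop_out),
                   label = sprintf("p=%.2g", .data$p_value)),
      inherit.aes = FALSE, vjust = -0.4, size = 3) +
    ggplot2::facet_wrap(~variant_class) +
    ggplot2::labs(x = "impact class", y = "proportion of variants",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @param counts An upset-count tibble from [upset_counts()].
#' @param top_n Number of patterns to show.
#' @export
plot_upset_counts <- function(counts, top_n = 20) {
  d <- head(counts, top_n)
  d$pattern <- factor(d$pattern, levels = d$pattern)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pattern, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "assembly presence pattern", y = "SV count") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 90, vjust = 0.5))
}
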