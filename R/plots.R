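#' Heatmap of a PABAK matrix
#'
#' Tiles genes (rows, in decreasing median-PABAK order) against method
#' pairs (columns), filled by the PABAK value; cells with no aligned calls
#' are left blank.
#'
#' @param object A [pabak_matrix()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pabak_matrix
#' @export
autoplot.pabak_matrix <- function(object, ...) {
  gm <- attr(object, "gene_medians")
  df <- as_tibble(object)
  df$gene <- factor(df$gene, levels = rev(gm$gene))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair, y = .data$gene,
                                   fill = .data$pabak)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::scale_fill_gradient2(
      low = "#b2182b", mid = "#f7f7f7", high = "#2166ac",
      midpoint = 0, limits = c(-0.5, 1), oob = scales_squish,
      na.value = "white", name = "PABAK"
    ) +
    ggplot2::labs(x = "method pair", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

# minimal squish (avoid a scales dependency for one helper)
scales_squish <- function(x, range = c(0, 1)) {
  pmin(pmax(x, range[1]), range[2])
}

#' Scatterplot of a Passing-Bablok fit
#'
#' Points, the identity line y = x (dashed), and the fitted regression
#' line.
#'
#' @param object A [passing_bablok()] fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot passing_bablok
#' @export
autoplot.passing_bablok <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey50") +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept, color = "#2166ac") +
    ggplot2::labs(
      x = "method x (copies)", y = "method y (copies)",
      subtitle = sprintf("y = %.3f x + %.3f (n = %d)",
                         object$slope, object$intercept, object$n)
    ) +
    ggplot2::theme_minimal()
}

#' Boxplots of relative discrepancies per method pair
#'
#' One box per pair of the per-sample relative discrepancy
#' `d = |y - x| / max(x, y)`; the closer to zero, the better the
#' interchangeability of the two methods.
#'
#' @param panel A [quantitative_panel()] result.
#' @return A ggplot object.
#' @export
plot_discrepancy <- function(panel) {
  points <- attr(panel, "points")
  if (is.null(points)) abort("panel lacks its points attribute.")
  df <- dplyr::bind_rows(
    purrr::imap(points, function(pts, pair) {
      tibble(pair = pair,
             d = relative_discrepancy(pts$x, pts$y)$d)
    })
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair, y = .data$d)) +
    ggplot2::geom_boxplot(fill = "#d1e5f0") +
    ggplot2::labs(x = "method pair", y = "relative discrepancy d") +
    ggplot2::theme_minimal()
}

#' Per-gene adjusted p-values from the differential table
#'
#' Dot plot of Holm-adjusted pooled p-values per gene with the 0.05 and
#' 0.1 (trend) reference lines.
#'
#' @param object A [differential_table()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cnv_differential
#' @export
autoplot.cnv_differential <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p_adjusted,
                                   y = stats::reorder(.data$gene,
                                                      -.data$p_adjusted))) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0.05, linetype = "dashed",
                        color = "#b2182b") +
    ggplot2::geom_vline(xintercept = 0.1, linetype = "dotted",
                        color = "grey50") +
    ggplot2::labs(x = "Holm-adjusted pooled p", y = NULL) +
    ggplot2::theme_minimal()
}
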