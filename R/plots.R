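#' Log-log scatter of a metric in two conditions
#'
#' One point per gene at (value in condition X, value in condition Y),
#' both axes log10, with the identity line `y = x` that genes fall on
#' when nothing changed. Zero values are floored before logging; the
#' floor is printed in the caption rather than silently dropping genes.
#'
#' @param tab A [splice_table()].
#' @param cond_x,cond_y Condition ids.
#' @param metric `"ie"` or `"rpkm"`.
#' @param floor Positive value substituted for zeros before logging.
#' @return A ggplot object.
#' @export
plot_metric_scatter <- function(tab, cond_x, cond_y, metric = c("ie", "rpkm"),
                                floor = 1e-4) {
  metric <- match.arg(metric)
  stopifnot(floor > 0)
  x <- tab[[paste0(metric, "_", cond_x)]]
  y <- tab[[paste0(metric, "_", cond_y)]]
  ok <- !is.na(x) & !is.na(y)
  df <- tibble::tibble(x = pmax(x[ok], floor), y = pmax(y[ok], floor))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "blue") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = paste0(toupper(metric), " (", cond_x, ")"),
      y = paste0(toupper(metric), " (", cond_y, ")"),
      caption = sprintf("zeros floored at %g for log axes", floor)
    ) +
    ggplot2::theme_minimal()
}

#' Box-and-whisker plot of diagonal-distance sets
#'
#' Distances near zero indicate minimal change between the compared
#' conditions; a shifted box marks a systematic defect.
#'
#' @param results A list of `comparison_result` objects (named or not).
#' @return A ggplot object.
#' @export
plot_distance_box <- function(results) {
  if (inherits(results, "comparison_result")) results <- list(results)
  labs <- names(results)
  if (is.null(labs)) {
    labs <- vapply(results, function(r)
      paste0(r$pair[["x"]], " vs ", r$pair[["y"]]), character(1))
  }
  df <- dplyr::bind_rows(lapply(seq_along(results), function(i) {
    tibble::tibble(comparison = labs[i],
                   distance = results[[i]]$distances$distance)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$comparison, y = .data$distance)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "signed diagonal distance") +
    ggplot2::theme_minimal()
}
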