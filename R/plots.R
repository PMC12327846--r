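#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a coverage track with called summits
#'
#' @param object A `peak_set`.
#' @param track Optional [coverage_track()] to draw under the summits.
#' @param region Optional `c(start, end)` window (0-based) to zoom into.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot peak_set
#' @export
autoplot.peak_set <- function(object, track = NULL, region = NULL, ...) {
  pk <- tidy(object)
  p <- ggplot2::ggplot()
  if (!is.null(track)) {
    df <- tibble::tibble(position = seq_along(track$values) - 1L,
                         depth = track$values)
    if (!is.null(region)) {
      df <- df[df$position >= region[1] & df$position < region[2], ]
    }
    p <- p + ggplot2::geom_area(
      data = df,
      ggplot2::aes(x = .data$position, y = .data$depth),
      fill = "grey70"
    )
  }
  if (!is.null(region)) {
    pk <- pk[pk$summit >= region[1] & pk$summit < region[2], ]
  }
  p +
    ggplot2::geom_vline(
      data = pk,
      ggplot2::aes(xintercept = .data$summit),
      colour = "firebrick", linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "genome position (bp)", y = "depth",
      title = sprintf("%s: %d peaks", object$sample %||% object$chrom,
                      nrow(object$peaks))
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of a replicate Pearson correlation matrix
#'
#' @param mat Matrix from [pearson_matrix()].
#' @return A ggplot object.
#' @export
plot_correlation_matrix <- function(mat) {
  df <- tibble::as_tibble(as.table(mat), .name_repair = "minimal")
  names(df) <- c("sample_a", "sample_b", "r")
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_a, .data$sample_b,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0.5,
                                  limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Scatter plot behind a correlation result
#'
#' @param object A `chap_correlation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot chap_correlation
#' @export
autoplot.chap_correlation <- function(object, ...) {
  df <- object$pairs
  xy <- names(df)[vapply(df, is.numeric, logical(1))][1:2]
  ggplot2::ggplot(df, ggplot2::aes(.data[[xy[1]]], .data[[xy[2]]])) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      title = sprintf("%s: %s r = %.3f, permutation p = %.3g",
                      object$label, object$method, object$estimate,
                      object$p_value)
    ) +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
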