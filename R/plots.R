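#' Manhattan plot of a genome scan
#'
#' Plots `-log10(p)` of the breed-S hypothesis (the primary statistic) along
#' the genome, with an optional genome-wide threshold line.
#'
#' @param object `ldla_scan` object.
#' @param threshold Optional genome-wide threshold to draw.
#' @param hypothesis One of "S", "all", "L".
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ldla_scan
#' @export
autoplot.ldla_scan <- function(object, threshold = NULL,
                               hypothesis = c("S", "all", "L"), ...) {
  hypothesis <- match.arg(hypothesis)
  ycol <- paste0("minus_log10_p_", hypothesis)
  df <- tibble::as_tibble(object)
  df$chrom_f <- factor(df$chrom)
  p <- ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$pos_mb, y = .data[[ycol]],
      colour = .data$chrom_f
    )
  ) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::facet_grid(
      cols = ggplot2::vars(.data$chrom_f),
      scales = "free_x", space = "free_x"
    ) +
    ggplot2::labs(
      x = "Position (Mb)",
      y = expression(-log[10](italic(p))),
      title = attr(object, "trait")
    ) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(
      yintercept = threshold,
      linetype = "dashed", colour = "black"
    )
  }
  p
}

#' Null-distribution plot of permutation maxima
#'
#' @param object `ldla_permnull` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ldla_permnull
#' @export
autoplot.ldla_permnull <- function(object, ...) {
  df <- tibble::tibble(max_logp = object$maxima)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$max_logp)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(
      xintercept = object$threshold, linetype = "dashed"
    ) +
    ggplot2::labs(
      x = expression("genome-wide max" ~ -log[10](italic(p))),
      y = "permutations"
    ) +
    ggplot2::theme_minimal()
}

#' @export
plot.ldla_scan <- function(x, ...) print(autoplot.ldla_scan(x, ...))

#' @export
plot.ldla_permnull <- function(x, ...) print(autoplot.ldla_permnull(x, ...))
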