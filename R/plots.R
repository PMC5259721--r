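#' Quantile-quantile plot of association p-values
#'
#' @param qq QQ tibble from [qq_manhattan_tables()] (`expected`, `observed`).
#' @return A ggplot object.
#' @export
plot_qq <- function(qq) {
  ggplot2::ggplot(qq, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p))) +
    ggplot2::theme_minimal()
}

#' Manhattan plot of per-variant association
#'
#' @param manhattan Manhattan tibble from [qq_manhattan_tables()].
#' @param threshold Optional p-value threshold drawn as a horizontal line.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(manhattan, threshold = NULL) {
  p <- ggplot2::ggplot(manhattan,
                       ggplot2::aes(x = .data$coord, y = .data$neg_log10_p,
                                    colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::labs(x = "Cumulative genome position (bp)",
                  y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(threshold),
                                 linetype = 2, colour = "red")
  }
  p
}

#' Null distribution of a matched-permutation enrichment test
#'
#' Histogram of the permutation null with the observed statistic marked.
#'
#' @param object An `enrich_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enrich_fit
#' @export
autoplot.enrich_fit <- function(object, ...) {
  df <- tibble::tibble(null_stat = object$null_stats)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null_stat)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed_stat, colour = "red") +
    ggplot2::labs(title = object$set_name,
                  subtitle = sprintf("fold = %.2f, empirical p = %.3g",
                                     object$fold, object$empirical_p),
                  x = "Null set statistic", y = "Replicates") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
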