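#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of replicate means
#'
#' Mean of each statistic over replicates with ±1 SD error bars.
#'
#' @param object An [lr_crossval()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lr_crossval <- function(object, ...) {
  s <- summarize_replicates(object)$summary
  ggplot2::ggplot(s, ggplot2::aes(x = stats::reorder(.data$statistic,
                                                     .data$mean),
                                  y = .data$mean)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "replicate mean ± SD") +
    ggplot2::theme_minimal()
}

#' Replicate distributions against theoretical expectations
#'
#' Boxplots of the LR statistics over replicates with the PEV/PEC-based
#' expected values overlaid as crossbars.
#'
#' @param object An [lr_sim_experiment()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lr_experiment <- function(object, ...) {
  g <- glance(object)
  long <- tidy(object)
  long <- long[long$statistic %in%
                 g$statistic[!is.na(g$expected)], , drop = FALSE]
  exp_df <- g[!is.na(g$expected), c("statistic", "expected")]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$statistic,
                                     y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::geom_point(data = exp_df,
                        ggplot2::aes(y = .data$expected),
                        colour = "red", shape = 4, size = 3) +
    ggplot2::labs(x = NULL, y = "replicate value",
                  caption = "red cross = mixed-model expectation") +
    ggplot2::theme_minimal()
}

#' Heatmap of correlations among replicate statistics
#'
#' @param x An [lr_crossval()] / [lr_sim_experiment()] object or a
#'   [summarize_replicates()] result.
#' @return A ggplot object.
#' @export
plot_lr_correlations <- function(x) {
  if (!inherits(x, "lr_cv_summary")) x <- summarize_replicates(x)
  cors <- x$correlations
  df <- tibble::as_tibble(cors, rownames = "stat_a")
  df <- tidyr::pivot_longer(df, -"stat_a", names_to = "stat_b",
                            values_to = "r")
  df$stat_a <- factor(df$stat_a, levels = rownames(cors))
  df$stat_b <- factor(df$stat_b, levels = colnames(cors))
  ggplot2::ggplot(df, ggplot2::aes(.data$stat_a, .data$stat_b,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "steelblue",
                                  mid = "white", high = "firebrick",
                                  na.value = "grey80") +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Scatter plot of a partial/whole EBV pair
#'
#' EBV from the whole data against EBV from the partial data, coloured by
#' subset, with the identity line and the fitted regression.
#'
#' @param pair Tibble with `ebv_partial`, `ebv_whole` and optionally
#'   `subset`.
#' @return A ggplot object.
#' @export
plot_ebv_pair <- function(pair) {
  p <- ggplot2::ggplot(pair, ggplot2::aes(x = .data$ebv_partial,
                                          y = .data$ebv_whole))
  if ("subset" %in% names(pair)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$subset),
                                 alpha = 0.6, size = 0.9)
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.6, size = 0.9)
  }
  p +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6, colour = "black") +
    ggplot2::labs(x = "EBV (partial data)", y = "EBV (whole data)") +
    ggplot2::theme_minimal()
}
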