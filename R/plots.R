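#' Convergence trace of a SAM fit
#'
#' Weight RMSE and adjacency error between adjacent iterations, on a log
#' scale, with the convergence threshold marked.
#'
#' @param fit A `sam_fit`.
#' @return A ggplot object.
#' @export
plot_trace <- function(fit) {
  stopifnot(inherits(fit, "sam_fit"))
  tr <- fit$trace
  df <- rbind(
    data.frame(iteration = tr$iteration, value = tr$weight_rmse,
               statistic = "weight RMSE"),
    data.frame(iteration = tr$iteration, value = tr$adjacency_error,
               statistic = "adjacency error"))
  df <- df[!is.na(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value,
                                   colour = .data$statistic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = fit$params$rmse_threshold,
                        linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "between-iteration difference",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Ranked gene-weight profile
#'
#' Gene weights sorted in descending order; the knee of this curve separates
#' the spatially informative genes from the rest.
#'
#' @param fit A `sam_fit`.
#' @param highlight Optional character vector of gene ids to mark.
#' @return A ggplot object.
#' @export
plot_weights <- function(fit, highlight = NULL) {
  wt <- weight_table(fit)
  wt$rank <- seq_len(nrow(wt))
  wt$highlighted <- if (is.null(highlight)) FALSE else wt$gene %in% highlight
  p <- ggplot2::ggplot(wt, ggplot2::aes(x = .data$rank, y = .data$weight)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::labs(x = "gene rank", y = "SAM weight") +
    ggplot2::theme_minimal()
  if (!is.null(highlight))
    p <- p + ggplot2::geom_point(data = wt[wt$highlighted, ],
                                 colour = "firebrick", size = 1)
  p
}

#' Metric-vs-corruption curves
#'
#' Mean +/- SD of each recorded metric as a function of the corruption
#' fraction.
#'
#' @param curve A `corruption_curve`.
#' @return A ggplot object.
#' @export
plot_corruption <- function(curve) {
  stopifnot(inherits(curve, "corruption_curve"))
  s <- curve$summary
  ggplot2::ggplot(s, ggplot2::aes(x = .data$f, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "corruption fraction f", y = "metric") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
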