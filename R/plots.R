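#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods
#'
#' `autoplot()` methods give quick diagnostic figures: the butterfly plot of
#' an averaged evoked potential, the lag-maximised correlation matrix, and a
#' circular layout of the thresholded directed graph.
#' [plot_cell_means()] shows the group mean and standard error of one network
#' metric across the pulse-by-side design.
#'
#' @param object A tepnet result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name tepnet-plots
NULL

#' @rdname tepnet-plots
#' @export
autoplot.tep_erp <- function(object, ...) {
  df <- tibble::as_tibble(t(object$data), .name_repair = "minimal")
  names(df) <- object$labels
  df$time_ms <- erp_times_ms(object)
  long <- tidyr::pivot_longer(df, -"time_ms", names_to = "channel",
                              values_to = "uV")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_ms, y = .data$uV,
                                     group = .data$channel)) +
    ggplot2::geom_line(alpha = 0.5, linewidth = 0.3) +
    ggplot2::labs(
      x = "time after test pulse (ms)", y = "amplitude (µV)",
      title = sprintf("Averaged evoked potential (%s / %s)",
                      object$condition$site, object$condition$pulse)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname tepnet-plots
#' @export
autoplot.tep_connectivity <- function(object, ...) {
  w <- object$weights
  long <- tibble::tibble(
    from = rep(rownames(w), times = ncol(w)),
    to = rep(colnames(w), each = nrow(w)),
    weight = as.vector(w)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$to, y = .data$from,
                                     fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = "lagging channel", y = "leading channel",
                  fill = "max c(τ)",
                  title = "Lag-maximised cross-correlation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @rdname tepnet-plots
#' @export
autoplot.tep_graph <- function(object, ...) {
  n <- length(object$labels)
  theta <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  nodes <- tibble::tibble(label = object$labels,
                          x = cos(theta), y = sin(theta))
  edges <- graph_edges(object)
  edges$x <- nodes$x[match(edges$src, nodes$label)]
  edges$y <- nodes$y[match(edges$src, nodes$label)]
  edges$xend <- nodes$x[match(edges$dst, nodes$label)]
  edges$yend <- nodes$y[match(edges$dst, nodes$label)]
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, alpha = .data$weight),
      arrow = ggplot2::arrow(length = ggplot2::unit(4, "pt")),
      linewidth = 0.3
    ) +
    ggplot2::geom_point(data = nodes, ggplot2::aes(x = .data$x, y = .data$y),
                        size = 2) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = 1.12 * .data$x, y = 1.12 * .data$y,
                                    label = .data$label), size = 2.6) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("Directed network (threshold %g, %d edges)",
                                  object$threshold, sum(object$adjacency)))
}

#' @rdname tepnet-plots
#' @param data Long metric tibble with `participant`, `group`, `side`,
#'   `pulse` and metric columns (e.g. `tep_study$metrics`).
#' @param metric Metric column to display.
#' @export
plot_cell_means <- function(data, metric = "mean_degree") {
  agg <- data |>
    dplyr::group_by(.data$group, .data$side, .data$pulse) |>
    dplyr::summarise(
      mean = mean(.data[[metric]]),
      se = stats::sd(.data[[metric]]) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$pulse, y = .data$mean,
                                    colour = .data$group,
                                    group = .data$group)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.2)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(0.2)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se,
                   ymax = .data$mean + .data$se),
      width = 0.15, position = ggplot2::position_dodge(0.2)
    ) +
    ggplot2::facet_wrap(~side) +
    ggplot2::labs(y = metric, x = "pulse type") +
    ggplot2::theme_minimal()
}

#' @rdname tepnet-plots
#' @param scores,labels Classifier scores and class labels, as in
#'   [roc_auc()].
#' @param positive Positive-class label.
#' @export
plot_roc <- function(scores, labels, positive = "ALD") {
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- purrr::map_dfr(thr, function(t) {
    pred <- scores >= t
    tibble::tibble(
      tpr = sum(pred & labels == positive) / sum(labels == positive),
      fpr = sum(pred & labels != positive) / sum(labels != positive)
    )
  })
  r <- roc_auc(scores, labels, positive)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (AUC = %.3f)", r$auc)) +
    ggplot2::theme_minimal()
}
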