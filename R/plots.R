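#' Plot an ROC curve
#'
#' @param object A `meg_roc` from [roc_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meg_roc <- function(object, ...) {
  curve <- dplyr::arrange(object$curve, 1 - .data$specificity, .data$sensitivity)
  ggplot2::ggplot(curve, ggplot2::aes(1 - .data$specificity, .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2c7fb8") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = object$name,
      subtitle = sprintf("AUC = %.2f", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a thresholded network
#'
#' Nodes on a circle, edges coloured by connection sign (red positive, blue
#' negative) with width proportional to |R|.
#'
#' @param object A `meg_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meg_network <- function(object, ...) {
  n <- object$n_nodes
  theta <- 2 * pi * (seq_len(n) - 1) / n
  nodes <- tibble::tibble(
    x = cos(theta), y = sin(theta),
    label = object$node_labels, role = object$node_roles
  )
  e <- object$edges
  edges <- tibble::tibble(
    x = nodes$x[e$from], y = nodes$y[e$from],
    xend = nodes$x[e$to], yend = nodes$y[e$to],
    weight = e$weight,
    sign = factor(ifelse(e$sign > 0, "positive", "negative"),
      levels = c("positive", "negative")
    )
  )
  p <- ggplot2::ggplot(nodes, ggplot2::aes(.data$x, .data$y))
  if (nrow(edges)) {
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(
        xend = .data$xend, yend = .data$yend,
        colour = .data$sign, linewidth = .data$weight
      ),
      alpha = 0.7
    )
  }
  p +
    ggplot2::geom_point(ggplot2::aes(fill = .data$role), shape = 21, size = 5) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
      nudge_y = 0.12, size = 3
    ) +
    ggplot2::scale_colour_manual(
      values = c(positive = "#d73027", negative = "#4575b4"), drop = FALSE
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 1.6), limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("%s band, %d edges (alpha = %g)", object$band, object$k_edges, object$alpha)
    ) +
    ggplot2::theme_void()
}

#' Boxplots of network metrics by group and band
#'
#' @param metrics A metrics table (as written by [run_metrics()]) with
#'   columns `band`, `group` and the parameter columns.
#' @param parameters Which parameters to facet (default the four network
#'   metrics).
#' @return A ggplot object.
#' @export
plot_band_metrics <- function(metrics, parameters = c("SA", "DA", "LA", "CA")) {
  long <- metrics |>
    tidyr::pivot_longer(dplyr::all_of(parameters),
      names_to = "parameter", values_to = "value"
    )
  ggplot2::ggplot(long, ggplot2::aes(.data$band, .data$value, fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, position = ggplot2::position_dodge(0.8)) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "Frequency band", y = "Value", fill = "Group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot a stretch of a recording
#'
#' @param rec A `meg_recording`.
#' @param t_lim Time window in seconds (default first 5 s).
#' @param channels Channel indices to show (default up to 6).
#' @return A ggplot object with annotated events shaded.
#' @export
plot_recording <- function(rec, t_lim = c(0, 5), channels = NULL) {
  if (is.null(channels)) channels <- seq_len(min(6, ncol(rec$data)))
  i <- seq(max(1, floor(t_lim[1] * rec$fs) + 1), min(nrow(rec$data), ceiling(t_lim[2] * rec$fs)))
  long <- tibble::tibble(
    t = rep((i - 1) / rec$fs, length(channels)),
    value = as.vector(rec$data[i, channels]),
    channel = rep(rec$node_labels[channels], each = length(i))
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$value))
  ann <- rec$annotations
  ann <- ann[ann$onset_s < t_lim[2] & ann$onset_s + ann$duration_s > t_lim[1], ]
  if (nrow(ann)) {
    p <- p + ggplot2::geom_rect(
      data = ann,
      ggplot2::aes(
        xmin = .data$onset_s, xmax = .data$onset_s + .data$duration_s,
        ymin = -Inf, ymax = Inf
      ),
      inherit.aes = FALSE, fill = "#fdae61", alpha = 0.4
    )
  }
  p +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, strip.position = "right") +
    ggplot2::labs(x = "Time (s)", y = "Amplitude (pT)") +
    ggplot2::theme_minimal()
}
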