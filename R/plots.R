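#' Plot the 2-D acoustic trait space
#'
#' Scatter plot of the embedded calls, coloured by any metadata column.
#'
#' @param emb Embedded call table ([embed_features()]).
#' @param colour Column name to colour by.
#' @return A ggplot object.
#' @export
plot_trait_space <- function(emb, colour = "individual") {
  ggplot2::ggplot(emb, ggplot2::aes(.data$dim1, .data$dim2,
                                    colour = .data[[colour]])) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::labs(x = "dimension 1", y = "dimension 2",
                  title = "Acoustic trait space") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.acoustic_space
#' @exportS3Method ggplot2::autoplot
autoplot.acoustic_space <- function(object, ...) {
  df <- tidyr::expand_grid(ix = seq_along(object$grid$x),
                           iy = seq_along(object$grid$y))
  df$x <- object$grid$x[df$ix]
  df$y <- object$grid$y[df$iy]
  df$density <- object$density[cbind(df$ix, df$iy)]
  df$hdr <- object$hdr_mask[cbind(df$ix, df$iy)]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$density)) +
    ggplot2::geom_contour(ggplot2::aes(z = as.numeric(.data$hdr)),
                          breaks = 0.5, colour = "white", linewidth = 0.3) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = sprintf("%d%% HDR area = %.2f units^2",
                                  round(100 * object$hdr_level),
                                  object$area),
                  x = "dimension 1", y = "dimension 2") +
    ggplot2::theme_minimal()
}

#' Plot methods for acoustic spaces and social networks
#'
#' `autoplot.acoustic_space` shows the kernel density with the HDR outline;
#' `autoplot.social_network` draws the 4-node weighted graph on a circular
#' layout with edge width proportional to weight.
#'
#' @param object An `acoustic_space` or `social_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot.acoustic_space
NULL

#' @rdname autoplot.acoustic_space
#' @exportS3Method ggplot2::autoplot
autoplot.social_network <- function(object, ...) {
  n <- length(object$birds)
  theta <- 2 * pi * (seq_len(n) - 1) / n
  nodes <- tibble(bird = object$birds, x = cos(theta), y = sin(theta))
  dyads <- utils::combn(seq_len(n), 2)
  edges <- tibble(
    x = nodes$x[dyads[1, ]], y = nodes$y[dyads[1, ]],
    xend = nodes$x[dyads[2, ]], yend = nodes$y[dyads[2, ]],
    weight = object$adjacency[cbind(dyads[1, ], dyads[2, ])])
  edges <- edges[edges$weight > 0, , drop = FALSE]
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(.data$x, .data$y, xend = .data$xend,
                                       yend = .data$yend,
                                       linewidth = .data$weight),
                          colour = "grey40") +
    ggplot2::geom_point(data = nodes, ggplot2::aes(.data$x, .data$y),
                        size = 6, colour = "steelblue") +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(.data$x * 1.25, .data$y * 1.25,
                                    label = .data$bird), size = 3) +
    ggplot2::scale_linewidth(range = c(0.3, 2.5)) +
    ggplot2::coord_equal(xlim = c(-1.5, 1.5), ylim = c(-1.5, 1.5)) +
    ggplot2::labs(title = sprintf("%s / %s (density %.2f)", object$flock,
                                  object$dimension,
                                  network_density(object))) +
    ggplot2::theme_void()
}

#' Plot vocal metrics by age class over recording blocks
#'
#' Mean and standard-error ribbons per age class and block for each of the
#' four vocal responses.
#'
#' @param metrics A [vocal_metrics()] table.
#' @return A ggplot object (facetted).
#' @export
plot_vocal_metrics <- function(metrics) {
  long <- tidyr::pivot_longer(
    metrics, dplyr::any_of(c("vocal_output", "diversity_change",
                             "plasticity", "convergence")),
    names_to = "measure", values_to = "value")
  long <- long[!is.na(long$value), ]
  summ <- long %>%
    dplyr::group_by(.data$measure, .data$age_class, .data$block) %>%
    dplyr::summarise(mean = mean(.data$value),
                     se = sd(.data$value) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(.data$block, .data$mean,
                                     colour = .data$age_class)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se),
                             position = ggplot2::position_dodge(0.2)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(0.2)) +
    ggplot2::facet_wrap(~ measure, scales = "free_y") +
    ggplot2::labs(x = "recording block", y = NULL, colour = "age class") +
    ggplot2::theme_minimal()
}
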