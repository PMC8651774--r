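# ggplot2 displays for frames and result objects.

#' @export
autoplot.rbc_frame <- function(object, ...) {
  px <- to_grayscale(object)$pixels
  df <- data.frame(
    row = rep(seq_len(nrow(px)), times = ncol(px)),
    col = rep(seq_len(ncol(px)), each = nrow(px)),
    intensity = as.vector(px)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column (px)", y = "row (px)", fill = "gray") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rbc_bland_altman <- function(object, ...) {
  g <- glance(object)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = g$bias, colour = "red",
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = c(g$loa_low, g$loa_high),
                        colour = "grey40", linetype = "dashed") +
    ggplot2::labs(x = "mean of methods",
                  y = if (object$mode == "percent") "difference (%)"
                      else "difference",
                  title = "Bland-Altman") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rbc_passing_bablok <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "black") +
    ggplot2::labs(title = sprintf("Passing-Bablok: y = %.4f x + %.4f",
                                  object$slope, object$intercept),
                  x = "comparator", y = "device") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rbc_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = 1 - .data$specificity,
                               y = .data$sensitivity)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("ROC (AUC = %.3f)", object$auc),
                  x = "1 - specificity", y = "sensitivity") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rbc_mountain <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$diff,
                                             y = .data$folded)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$center, colour = "red",
                        linetype = "dashed") +
    ggplot2::labs(title = "Mountain plot", x = "difference",
                  y = "folded percentile") +
    ggplot2::theme_minimal()
}

#' Scatter dot plot of per-cell deformability
#'
#' @param pairs an `rbc_match` or a tibble with a `dr` column.
#' @return a ggplot.
#' @export
plot_deformability <- function(pairs) {
  tab <- if (inherits(pairs, "rbc_match")) pairs$pairs else pairs
  ggplot2::ggplot(tab, ggplot2::aes(x = "", y = .data$dr)) +
    ggplot2::geom_jitter(width = 0.2, alpha = 0.5, size = 0.8) +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.4, colour = "red") +
    ggplot2::labs(x = NULL, y = "deformation index Dr") +
    ggplot2::theme_minimal()
}
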