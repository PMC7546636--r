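# ggplot2 visualisations for the main result types.

#' Plot an empirical spectral density
#'
#' Histogram-style density of a largest-eigenvalue sample; with
#' `log_log = TRUE` a log-log rendering where a power-law tail is a
#' straight line.
#'
#' @param object An `esd` tibble from [esd()].
#' @param log_log Use log-log axes (default FALSE).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.esd <- function(object, log_log = FALSE, ...) {
  df <- dplyr::filter(object, .data$density > 0)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$bin_center, .data$density)) +
    ggplot2::labs(x = expression(lambda[max]), y = "density") +
    ggplot2::theme_minimal()
  if (log_log) {
    p + ggplot2::geom_point() +
      ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  } else {
    p + ggplot2::geom_col(width = df$bin_right - df$bin_left,
                          fill = "grey40")
  }
}

#' @export
autoplot.eigen_sample <- function(object, log_log = FALSE, ...) {
  autoplot.esd(esd(object), log_log = log_log, ...)
}

#' Plot a tensor profile as a pixel-by-time heat map
#'
#' @param tp A [tensor_profile].
#' @param max_pixels,max_frames Downsampling caps for display.
#' @return A ggplot.
#' @export
plot_profile <- function(tp, max_pixels = 200, max_frames = 500) {
  stopifnot(inherits(tp, "tensor_profile"))
  ri <- unique(round(seq(1, nrow(tp$P), length.out = min(max_pixels, nrow(tp$P)))))
  ci <- unique(round(seq(1, ncol(tp$P), length.out = min(max_frames, ncol(tp$P)))))
  df <- expand.grid(pixel = ri, frame = ci)
  df$value <- tp$P[cbind(df$pixel, df$frame)]
  ggplot2::ggplot(df, ggplot2::aes(.data$frame, .data$pixel,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = "frame", y = "pixel", fill = "z") +
    ggplot2::theme_minimal()
}

#' ROC curve of pooled leave-one-out segment scores
#'
#' @param object A `loo_result` from [loo_xv()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.loo_result <- function(object, ...) {
  sp <- object$segment_predictions
  truth <- as_label01(sp$truth)
  ord <- order(sp$score, decreasing = TRUE)
  tpr <- c(0, cumsum(truth[ord] == 1) / sum(truth == 1))
  fpr <- c(0, cumsum(truth[ord] == 0) / sum(truth == 0))
  ggplot2::ggplot(tibble(fpr = fpr, tpr = tpr),
                  ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = 2, colour = "grey60") +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("Pooled segment ROC (AUC = %.3f)",
                                  object$metrics$auc)) +
    ggplot2::theme_minimal()
}

#' Density of synthetic cohort eigenvalue samples by group
#'
#' @param object A `cohort_features` tibble.
#' @param ... Unused.
#' @return A ggplot (log-scale x).
#' @export
autoplot.cohort_features <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$value, colour = .data$group)) +
    ggplot2::geom_density() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(lambda[max]), y = "density") +
    ggplot2::theme_minimal()
}
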