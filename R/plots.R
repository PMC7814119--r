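#' Plot clock weights
#'
#' Lollipop chart of the nonzero clock weights, largest magnitudes first.
#'
#' @param object A `chick_clock`.
#' @param n_top Show at most this many features (default 30).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chick_clock <- function(object, n_top = 30, ...) {
  d <- head(tidy(object), n_top)
  d$feature <- factor(d$feature, levels = rev(d$feature))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$weight, y = .data$feature)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$weight,
                                       yend = .data$feature), linewidth = 0.3) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "clock weight (days per methylation unit)", y = NULL,
                  title = sprintf("%s clock: %d markers", object$feature_kind,
                                  length(object$weights))) +
    ggplot2::theme_minimal()
}

#' Plot cross-validated age predictions
#'
#' Out-of-fold predicted versus chronological age, colored by tissue, with
#' the identity line; the panel title reports the pooled RMSE.
#'
#' @param object A `chick_clock_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chick_clock_cv <- function(object, ...) {
  d <- object$predictions
  ggplot2::ggplot(d, ggplot2::aes(x = .data$age_days, y = .data$predicted_age,
                                  color = .data$tissue)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "chronological age (days)", y = "predicted age (days)",
                  title = sprintf("%d-fold CV, RMSE %.2f days",
                                  object$k_folds, object$rmse)) +
    ggplot2::theme_minimal()
}

#' Plot age-acceleration deltas by group
#'
#' Box-and-point plot of predicted minus chronological age per group.
#'
#' @param results An acceleration tibble from [age_acceleration()].
#' @return A ggplot object.
#' @export
plot_age_acceleration <- function(results) {
  ggplot2::ggplot(results, ggplot2::aes(x = .data$group, y = .data$delta)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "age acceleration (days)") +
    ggplot2::theme_minimal()
}

#' Violin plot of sliding-window methylation distributions
#'
#' The genome-wide methylation-landscape summary: distribution of window
#' mean methylation per sample.
#'
#' @param windows Named list of window tibbles
#'   (from [sliding_window_methylation()]), names used as sample labels;
#'   a single tibble is also accepted.
#' @return A ggplot object.
#' @export
plot_window_methylation <- function(windows) {
  if (is.data.frame(windows)) windows <- list(sample = windows)
  d <- dplyr::bind_rows(windows, .id = "sample")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample, y = .data$mean_methylation)) +
    ggplot2::geom_violin(fill = "lightblue") +
    ggplot2::labs(x = NULL, y = "window mean methylation") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
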