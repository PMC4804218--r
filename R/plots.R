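#' Plot within-fold heterogeneity across folds
#'
#' Mean within-fold TM_max score per fold with one-SD whiskers (left panel
#' style) — homogeneous folds sit near 1, heterogeneous folds fall toward
#' 0.6-0.7 with wider whiskers.
#'
#' @param profiles Named list of `fold_profile`s or a [heterogeneity_table()].
#' @returns A ggplot.
#' @export
plot_heterogeneity <- function(profiles) {
  het <- if (is.data.frame(profiles)) profiles else heterogeneity_table(profiles)
  het |>
    dplyr::arrange(dplyr::desc(.data$mean_x)) |>
    dplyr::mutate(fold_id = factor(.data$fold_id, levels = .data$fold_id)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$fold_id, y = .data$mean_x)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_x - .data$sd_x,
                                          ymax = pmin(.data$mean_x + .data$sd_x, 1)),
                             linewidth = 0.3, size = 0.3) +
    ggplot2::labs(x = "fold", y = "within-fold TM_max (mean ± SD)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @exportS3Method ggplot2::autoplot
autoplot.fold_profile <- function(object, ...) {
  tibble::tibble(x = object$x) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$x)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey40") +
    ggplot2::labs(title = sprintf("fold %s (%s)", object$fold_id, object$mode),
                  x = "within-fold TM_max", y = "domains") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.rjmcmc_gmm <- function(object, ...) {
  tibble::tibble(sweep = seq_along(object$k_trace), k = object$k_trace) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$sweep, y = .data$k)) +
    ggplot2::geom_step(linewidth = 0.2) +
    ggplot2::labs(x = "sweep", y = "number of mixture components k") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.posterior_predictive <- function(object, ...) {
  tibble::tibble(x = object$draws) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$x)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey40") +
    ggplot2::labs(x = "predictive TM_max draw", y = "count") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.holdout_result <- function(object, ...) {
  object$summary |>
    ggplot2::ggplot(ggplot2::aes(x = .data$method, y = .data$mean_disagreement)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = pmax(.data$mean_disagreement - .data$sd_disagreement, 0),
      ymax = .data$mean_disagreement + .data$sd_disagreement), width = 0.2) +
    ggplot2::labs(x = NULL,
                  y = "fraction inconsistent with original classification") +
    ggplot2::theme_minimal()
}
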