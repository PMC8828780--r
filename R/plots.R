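# ggplot2 autoplot() methods for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-cell-type accuracy of an evaluation report
#'
#' Bar panel of RMSE (percentage points) and R^2 per cell type.
#'
#' @param object An `eval_report` from [evaluate_estimates()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- tibble::as_tibble(object) %>%
    tidyr::pivot_longer(c("r2", "rmse"), names_to = "metric") %>%
    dplyr::mutate(
      metric = dplyr::recode(.data$metric, r2 = "R²", rmse = "RMSE (pp)"),
      cell_type = factor(.data$cell_type, levels = cell_types()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell_type, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), ncol = 1,
                        scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Deconvolution accuracy per cell type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot estimated cell composition per sample
#'
#' Stacked bars of the normalized proportions.
#'
#' @param object A `deconv_result` from [deconvolve_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.deconv_result <- function(object, ...) {
  df <- tidy(object) %>%
    dplyr::mutate(cell_type = factor(.data$cell_type, levels = cell_types()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id,
                                   y = .data$normalized,
                                   fill = .data$cell_type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Estimated proportion", fill = "Cell type",
                  title = "Cell-mixture deconvolution estimates") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the optimization trace of an IDOL run
#'
#' Per-iteration mean RMSE of the sampled library with the best-so-far
#' envelope.
#'
#' @param object An `idol_state` from [run_idol()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.idol_state <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(x = .data$iteration)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_rmse),
                       colour = "grey60") +
    ggplot2::geom_step(ggplot2::aes(y = .data$best_rmse),
                       colour = "firebrick") +
    ggplot2::labs(x = "Iteration", y = "Mean RMSE (pp)",
                  title = sprintf("IDOL optimization, S = %d",
                                  object$config$library_size),
                  subtitle = "grey: sampled library; red: best so far") +
    ggplot2::theme_minimal()
}

#' Plot the library-size grid of an IDOL grid search
#'
#' Mean RMSE of the best library per size, the optimum highlighted.
#'
#' @param object An `idol_grid` from [run_idol_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.idol_grid <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$library_size, y = .data$mean_rmse)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$optimal), size = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey30"),
                                 guide = "none") +
    ggplot2::labs(x = "Library size (CpGs)", y = "Mean RMSE (pp)",
                  title = "IDOL library-size grid") +
    ggplot2::theme_minimal()
}
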