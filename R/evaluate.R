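#' Score deconvolution estimates against known proportions
#'
#' For every cell type, compares estimated to true proportions across
#' samples and reports the root-mean-square error in percentage points,
#' \deqn{RMSE_k = 100 \sqrt{\tfrac1n \sum_i (\hat w_{ik} - w_{ik})^2},}
#' and the squared Pearson correlation \eqn{R^2_k} between the estimated and
#' true columns. \eqn{R^2} is the convention used when validating estimates
#' against flow cytometry in scatter plots; it is undefined (reported `NA`)
#' when the truth column has zero variance, and such types are excluded from
#' `mean_r2` but still contribute their RMSE to `mean_rmse`.
#'
#' @param estimates A `deconv_result` from [deconvolve_matrix()], or a plain
#'   samples x 12 matrix of proportions.
#' @param truth A [mixture_truth()] with the same samples.
#' @param which For a `deconv_result`, which proportions to score:
#'   `"normalized"` (default; rows rescaled to sum 1) or `"raw"`.
#' @return An `eval_report`: a tibble with one row per cell type
#'   (`cell_type`, `r2`, `rmse`, `r2_defined`) and attributes `mean_r2`,
#'   `mean_rmse` (retrieved with [glance()]).
#' @export
#' @examples
#' truth <- mixture_truth(matrix(1 / 12, 2, 12,
#'   dimnames = list(c("m1", "m2"), cell_types())))
#' est <- unclass(truth)
#' est[, "Neu"] <- est[, "Neu"] + c(0.01, -0.01)
#' evaluate_estimates(est, truth)
evaluate_estimates <- function(estimates, truth,
                               which = c("normalized", "raw")) {
  which <- match.arg(which)
  w_hat <- if (inherits(estimates, "deconv_result")) {
    if (which == "normalized") estimates$normalized else estimates$raw
  } else {
    as.matrix(estimates)
  }
  w <- unclass(truth)
  if (!setequal(rownames(w_hat), rownames(w))) {
    stop("Estimates and truth cover different samples: ",
         paste(utils::head(c(setdiff(rownames(w_hat), rownames(w)),
                             setdiff(rownames(w), rownames(w_hat))), 5),
               collapse = ", "), call. = FALSE)
  }
  w_hat <- w_hat[rownames(w), colnames(w), drop = FALSE]
  if (nrow(w) < 2) stop("Need at least 2 samples to evaluate", call. = FALSE)

  per_type <- purrr::map_dfr(colnames(w), function(k) {
    d <- w_hat[, k] - w[, k]
    rmse <- 100 * sqrt(mean(d^2))
    defined <- stats::sd(w[, k]) > 0 && stats::sd(w_hat[, k]) > 0
    r2 <- if (defined) stats::cor(w_hat[, k], w[, k])^2 else NA_real_
    tibble::tibble(cell_type = k, r2 = r2, rmse = rmse, r2_defined = defined)
  })
  structure(per_type,
            class = c("eval_report", class(per_type)),
            mean_r2 = mean(per_type$r2, na.rm = TRUE),
            mean_rmse = mean(per_type$rmse))
}

#' One-line summary of an evaluation report
#'
#' @param x An `eval_report` from [evaluate_estimates()].
#' @param ... Unused.
#' @return Tibble with `mean_r2` (mean over cell types with defined
#'   \eqn{R^2}), `mean_rmse` (percentage points), `n_types`,
#'   `n_r2_undefined`.
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(
    mean_r2 = attr(x, "mean_r2"),
    mean_rmse = attr(x, "mean_rmse"),
    n_types = nrow(x),
    n_r2_undefined = sum(!x$r2_defined))
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: mean R2 = %.4f, mean RMSE = %.4f pp\n",
              attr(x, "mean_r2"), attr(x, "mean_rmse")))
  NextMethod()
}

# broom-style generics, defined here so the package does not depend on broom
#' Turn a fitted object into a tidy tibble
#' @param x Object to tidy.
#' @param ... Method-specific arguments.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
tidy.eval_report <- function(x, ...) tibble::as_tibble(x)

#' One-row model summary
#' @param x Object to summarise.
#' @param ... Method-specific arguments.
#' @export
glance <- function(x, ...) UseMethod("glance")
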