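# Constrained projection / quadratic programming (CP/QP): estimate the cell
# proportions w of a mixed sample from its beta vector y and the library's
# mean-methylation matrix X by
#   minimize ||y - X w||^2  subject to  w >= 0,  sum(w) <= 1.
# The problem is a convex QP solved with quadprog; the normalized estimate
# w / sum(w) is what downstream profiling uses.

# Solve from precomputed crossproducts (XtX is K x K). A tiny ridge is added
# if XtX is numerically rank-deficient (e.g. duplicate cell-type columns);
# the QP remains well-posed and a degeneracy warning is raised upstream.
cpqp_solve_cross <- function(XtX, Xty) {
  K <- ncol(XtX)
  Amat <- cbind(rep(-1, K), diag(K))
  bvec <- c(-1, rep(0, K))
  sol <- tryCatch(
    quadprog::solve.QP(XtX, Xty, Amat, bvec),
    error = function(e) {
      ridge <- max(diag(XtX)) * 1e-8 + 1e-12
      quadprog::solve.QP(XtX + diag(ridge, K), Xty, Amat, bvec)
    })
  w <- sol$solution
  w[w < 0] <- 0           # clip solver noise at the active bounds
  s <- sum(w)
  if (s > 1) w <- w / s   # numeric overshoot of the sum constraint
  names(w) <- colnames(XtX)
  w
}

#' Deconvolve a single beta vector by constrained projection
#'
#' Estimates the mixture proportions of one sample over the 12 cell types by
#' non-negative, sum-constrained least squares against the library means
#' (see the package vignette for the model). Missing entries in `y` are
#' dropped together with the corresponding library rows.
#'
#' @param y Named numeric vector of beta values covering the library probes
#'   (`NA` entries are dropped).
#' @param lib A `deconv_library`.
#' @return List with `raw` (the constrained solution, `sum(raw) <= 1`),
#'   `normalized` (`raw / sum(raw)`, `NA` if the raw sum is 0), `residual`
#'   (residual norm of the fit) and `n_probes_used`.
#' @export
#' @examples
#' ref <- simulate_reference(sim_config(markers_per_type = 5,
#'   n_background_probes = 20, seed = 1, noise_sd = 0, purity_range = c(1, 1)))
#' lib <- auto_select_library(ref$reference, n_per_direction = 5)
#' y <- lib$means[, "Neu"]
#' round(cpqp_deconvolve(y, lib)$raw, 3)
cpqp_deconvolve <- function(y, lib) {
  X <- lib$means
  if (!is.null(names(y))) {
    missing_probes <- setdiff(rownames(X), names(y))
    if (length(missing_probes) == nrow(X)) {
      stop("No library probe present in the target vector", call. = FALSE)
    }
    y <- y[rownames(X)]
  } else if (length(y) != nrow(X)) {
    stop("Unnamed target vector must match the library length", call. = FALSE)
  }
  keep <- !is.na(y)
  if (!any(keep)) stop("Target vector is entirely missing", call. = FALSE)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  if (qr(X)$rank < ncol(X)) {
    warning("Library design matrix is rank-deficient; estimates may not be unique")
  }
  w <- cpqp_solve_cross(crossprod(X), crossprod(X, y)[, 1])
  s <- sum(w)
  list(raw = w,
       normalized = if (s > 0) w / s else stats::setNames(rep(NA_real_, length(w)), names(w)),
       residual = sqrt(sum((y - X %*% w)^2)),
       n_probes_used = sum(keep))
}

#' Deconvolve every sample of a beta matrix
#'
#' Runs [cpqp_deconvolve()] per sample. Library probes absent from the
#' matrix or missing in a given sample are dropped for that sample only, so
#' mixed-platform inputs lose no samples. Each sample's library call rate
#' (probes used / library size) is recorded: samples below `min_call_rate`
#' are not deconvolved (status `"error"`, estimates `NA`) and samples
#' between the floor and `warn_call_rate` are flagged, as low call rates
#' degrade estimate quality.
#'
#' @param targets A [beta_matrix()] of mixed samples.
#' @param lib A `deconv_library`.
#' @param min_call_rate Minimum usable fraction of library probes
#'   (default 0.80).
#' @param warn_call_rate Call rate below which a sample is flagged
#'   (default 0.95).
#' @return A `deconv_result`: list with matrices `raw` and `normalized`
#'   (samples x 12), vector `residual`, and tibble `samples` (`sample_id`,
#'   `call_rate`, `status`, `message`). Use [tidy()] for a long tibble and
#'   [glance()] for a one-row summary.
#' @export
deconvolve_matrix <- function(targets, lib, min_call_rate = 0.80,
                              warn_call_rate = 0.95) {
  X_all <- lib$means
  shared <- intersect(rownames(X_all), rownames(targets))
  n_lib <- nrow(X_all)
  vals <- unclass(targets)[shared, , drop = FALSE]
  n <- ncol(vals)
  K <- ncol(X_all)
  raw <- norm <- matrix(NA_real_, n, K,
                        dimnames = list(colnames(vals), colnames(X_all)))
  residual <- stats::setNames(rep(NA_real_, n), colnames(vals))
  status <- character(n); msg <- character(n)
  call_rate <- numeric(n)
  for (j in seq_len(n)) {
    y <- vals[, j]
    keep <- !is.na(y)
    call_rate[j] <- sum(keep) / n_lib
    if (call_rate[j] < min_call_rate) {
      status[j] <- "error"
      msg[j] <- sprintf("call rate %.2f below floor %.2f",
                        call_rate[j], min_call_rate)
      next
    }
    fit <- cpqp_deconvolve(y[keep], lib)
    raw[j, ] <- fit$raw
    norm[j, ] <- fit$normalized
    residual[j] <- fit$residual
    if (call_rate[j] < warn_call_rate) {
      status[j] <- "warning"
      msg[j] <- sprintf("call rate %.2f below %.2f", call_rate[j],
                        warn_call_rate)
    } else {
      status[j] <- "ok"
      msg[j] <- ""
    }
  }
  if (any(status == "error")) {
    warning(sprintf("%d sample(s) below the call-rate floor were not deconvolved",
                    sum(status == "error")))
  }
  structure(
    list(raw = raw, normalized = norm, residual = residual,
         samples = tibble::tibble(sample_id = colnames(vals),
                                  call_rate = call_rate, status = status,
                                  message = msg),
         library_size = n_lib),
    class = "deconv_result")
}

#' @export
print.deconv_result <- function(x, ...) {
  cat(sprintf("deconv_result: %d samples x %d cell types (%d ok, %d warned, %d errored)\n",
              nrow(x$raw), ncol(x$raw), sum(x$samples$status == "ok"),
              sum(x$samples$status == "warning"),
              sum(x$samples$status == "error")))
  invisible(x)
}

#' Long-format cell-proportion estimates
#'
#' @param x A `deconv_result`.
#' @param ... Unused.
#' @return Tibble with `sample_id`, `cell_type`, `raw`, `normalized`.
#' @export
tidy.deconv_result <- function(x, ...) {
  raw_l <- tibble::as_tibble(x$raw, rownames = "sample_id") %>%
    tidyr::pivot_longer(-"sample_id", names_to = "cell_type",
                        values_to = "raw")
  norm_l <- tibble::as_tibble(x$normalized, rownames = "sample_id") %>%
    tidyr::pivot_longer(-"sample_id", names_to = "cell_type",
                        values_to = "normalized")
  dplyr::left_join(raw_l, norm_l, by = c("sample_id", "cell_type"))
}

#' @export
glance.deconv_result <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$raw),
    n_ok = sum(x$samples$status == "ok"),
    n_warned = sum(x$samples$status == "warning"),
    n_errored = sum(x$samples$status == "error"),
    median_call_rate = stats::median(x$samples$call_rate),
    median_residual = stats::median(x$residual, na.rm = TRUE))
}

#' DNA methylation purity of a sorted reference sample
#'
#' Projects a purified sample back onto the library ("reverse
#' deconvolution") and returns the normalized proportion estimated for its
#' own labeled cell type. A perfectly pure sample yields 1; contamination by
#' other cell types lowers the value accordingly.
#'
#' @param y Named beta vector of the reference sample over the library
#'   probes.
#' @param lib A `deconv_library`.
#' @param labeled_type The cell type the sample was sorted as.
#' @return Purity fraction in [0, 1].
#' @export
methylation_purity <- function(y, lib, labeled_type) {
  validate_cell_types(labeled_type)
  if (!labeled_type %in% colnames(lib$means)) {
    stop(sprintf("Labeled type '%s' is not a column of the library",
                 labeled_type), call. = FALSE)
  }
  fit <- cpqp_deconvolve(y, lib)
  unname(fit$normalized[labeled_type])
}

#' Screen reference samples by DNA methylation purity
#'
#' Estimates every reference sample's methylation purity against the
#' library and applies the inclusion rule: a sample passes only when its
#' purity is strictly greater than `threshold` (default 0.85, i.e. purity
#' higher than 85%). The report also names the strongest contaminant type.
#'
#' @param ref A [reference_set()].
#' @param lib A `deconv_library`.
#' @param threshold Purity threshold (strict inequality; default 0.85).
#' @return Tibble with `sample_id`, `labeled_type`, `purity`,
#'   `top_contaminant`, `contaminant_fraction`, `pass`.
#' @export
screen_reference_purity <- function(ref, lib, threshold = 0.85) {
  fit <- deconvolve_matrix(ref$betas, lib)
  purrr::map_dfr(colnames(ref$betas), function(s) {
    w <- fit$normalized[s, ]
    lab <- ref$labels[[s]]
    others <- w[setdiff(names(w), lab)]
    top <- names(others)[which.max(others)]
    tibble::tibble(
      sample_id = s, labeled_type = lab, purity = unname(w[lab]),
      top_contaminant = top, contaminant_fraction = unname(others[top]),
      pass = unname(w[lab]) > threshold)
  })
}
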