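#' Construct a beta-value matrix
#'
#' A `beta_matrix` is a plain numeric matrix of methylation beta values
#' (probes in rows, samples in columns) carrying a class attribute so that
#' methods can dispatch on it. Values must lie in [0, 1]; `NA` marks entries
#' masked by quality control. Row and column names are mandatory and unique:
#' they are the probe and sample identifiers used for all alignment.
#'
#' @param values Numeric matrix, probes x samples, entries in [0, 1] or `NA`.
#' @param probe_ids,sample_ids Optional identifier vectors; defaults to the
#'   existing dimnames of `values`.
#' @return A `beta_matrix` object.
#' @export
#' @examples
#' b <- beta_matrix(matrix(c(0.1, 0.9, 0.5, 0.4), 2, 2,
#'                         dimnames = list(c("cg1", "cg2"), c("s1", "s2"))))
#' dim(b)
beta_matrix <- function(values, probe_ids = rownames(values),
                        sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(probe_ids) || is.null(sample_ids)) {
    stop("beta_matrix requires probe and sample identifiers", call. = FALSE)
  }
  rownames(values) <- as.character(probe_ids)
  colnames(values) <- as.character(sample_ids)
  validate_beta_matrix(values)
  structure(values, class = c("beta_matrix", "matrix", "array"))
}

validate_beta_matrix <- function(values) {
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop("Duplicate probe ID(s): ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    dup <- unique(colnames(values)[duplicated(colnames(values))])
    stop("Duplicate sample ID(s): ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.na(values) & (values < 0 | values > 1))
  if (length(bad) > 0) {
    i <- arrayInd(bad[1], dim(values))
    stop(sprintf(
      "Beta values must lie in [0, 1]; e.g. probe '%s', sample '%s' has %g",
      rownames(values)[i[1]], colnames(values)[i[2]], values[bad[1]]),
      call. = FALSE)
  }
  invisible(values)
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d probes x %d samples (%d missing entries)\n",
              nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

#' Bundle sorted-cell reference samples with their cell-type labels
#'
#' A `reference_set` pairs a [beta_matrix()] of purified (sorted) leukocyte
#' samples with a label assigning each sample to one of the 12 canonical cell
#' types, and optionally a measured purity fraction per sample. It is the
#' input to marker discovery ([one_vs_rest_tstats()]), library construction
#' ([auto_select_library()], [assemble_library()]) and the methylation-purity
#' screen ([screen_reference_purity()]).
#'
#' Cell types represented by fewer than two samples are permitted (a library
#' mean can still be formed) but are reported in the `underpowered` field
#' because one-vs-rest t-tests need at least two samples per group.
#'
#' @param betas A [beta_matrix()] of the reference samples.
#' @param labels Named character vector or a data frame with columns
#'   `sample_id` and `cell_type`, mapping every sample to a canonical code.
#' @param purity Optional named numeric vector of measured purity fractions
#'   in [0, 1] (for example flow-cytometry purity).
#' @return A `reference_set` object (list with `betas`, `labels`, `purity`,
#'   `underpowered`).
#' @export
reference_set <- function(betas, labels, purity = NULL) {
  if (!inherits(betas, "beta_matrix")) betas <- beta_matrix(betas)
  if (is.data.frame(labels)) {
    labels <- stats::setNames(as.character(labels$cell_type),
                              as.character(labels$sample_id))
  }
  missing_lab <- setdiff(colnames(betas), names(labels))
  if (length(missing_lab) > 0) {
    stop("Samples without a cell-type label: ",
         paste(utils::head(missing_lab, 5), collapse = ", "), call. = FALSE)
  }
  labels <- labels[colnames(betas)]
  validate_cell_types(labels)
  if (!is.null(purity)) {
    purity <- purity[colnames(betas)]
    if (any(!is.na(purity) & (purity < 0 | purity > 1))) {
      stop("Purity fractions must lie in [0, 1]", call. = FALSE)
    }
  }
  counts <- table(factor(labels, levels = cell_types()))
  under <- names(counts)[counts > 0 & counts < 2]
  structure(
    list(betas = betas, labels = labels, purity = purity,
         underpowered = under),
    class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  counts <- table(factor(x$labels, levels = cell_types()))
  cat(sprintf("reference_set: %d probes, %d samples, %d cell types\n",
              nrow(x$betas), ncol(x$betas), sum(counts > 0)))
  print(counts)
  invisible(x)
}

#' Per-type sample counts of a reference set
#'
#' @param ref A [reference_set()].
#' @return Tibble with columns `cell_type` and `n_samples`.
#' @export
reference_counts <- function(ref) {
  counts <- table(factor(ref$labels, levels = cell_types()))
  tibble::tibble(cell_type = names(counts), n_samples = as.integer(counts))
}

#' Known mixture proportions (ground truth)
#'
#' Stores the true cell proportions of artificial mixtures: one row per
#' sample, one column per canonical cell type, rows summing to one. Used to
#' score deconvolution estimates in [evaluate_estimates()] and to drive the
#' IDOL optimizer.
#'
#' @param proportions Numeric matrix or data frame, samples x 12, with
#'   sample IDs as row names and the canonical cell types as columns.
#' @param tol Tolerance on the row sums (default `1e-9`).
#' @return A `mixture_truth` object (matrix with class attribute).
#' @export
mixture_truth <- function(proportions, tol = 1e-9) {
  p <- as.matrix(proportions)
  storage.mode(p) <- "double"
  if (is.null(rownames(p))) stop("mixture_truth needs sample IDs", call. = FALSE)
  if (!identical(colnames(p), cell_types())) {
    if (is.null(colnames(p)) || !setequal(colnames(p), cell_types())) {
      stop("mixture_truth needs exactly the 12 canonical cell-type columns",
           call. = FALSE)
    }
    p <- p[, cell_types(), drop = FALSE]
  }
  if (any(p < 0)) stop("Mixture proportions must be non-negative", call. = FALSE)
  rs <- rowSums(p)
  if (any(abs(rs - 1) > tol)) {
    stop(sprintf("Mixture proportion rows must sum to 1 (max deviation %g)",
                 max(abs(rs - 1))), call. = FALSE)
  }
  structure(p, class = c("mixture_truth", "matrix", "array"))
}
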