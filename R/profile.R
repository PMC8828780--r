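# The derived immune-profile layer: from 12 normalized base proportions the
# package derives 7 hierarchical aggregates (19 proportions total), 19
# absolute counts when a total leukocyte count is supplied, and 18 named
# cell ratios -- 56 variables per sample with counts, 37 without.

aggregate_names <- function() names(cell_type_branches())

profile_proportion_names <- function() c(cell_types(), aggregate_names())

#' The 18 default immune-profile ratios
#'
#' A frozen, named ratio set so profiles are reproducible across analyses:
#' NLR (neutrophil to lymphocyte ratio) and other lineage balances, the
#' per-lineage and overall naive-to-memory ratios, within-branch shares
#' (e.g. Treg share of CD4T, Eos and Bas shares of granulocytes) and the
#' major-compartment shares of total leukocytes. Each entry maps the ratio
#' name to its numerator and denominator among the 19 profile proportions.
#'
#' @return Named list of `c(numerator, denominator)` pairs. Numerators given
#'   as `"+"`-joined type codes are sums.
#' @export
profile_ratio_definitions <- function() {
  list(
    NLR           = c("Neu", "Lymphoid"),
    CD4T_CD8T     = c("CD4T", "CD8T"),
    Bnv_Bmem      = c("Bnv", "Bmem"),
    CD4nv_CD4mem  = c("CD4nv", "CD4mem"),
    CD8nv_CD8mem  = c("CD8nv", "CD8mem"),
    naive_memory  = c("Bnv+CD4nv+CD8nv", "Bmem+CD4mem+CD8mem"),
    Lymph_Myeloid = c("Lymphoid", "Myeloid"),
    Treg_CD4T     = c("Treg", "CD4T"),
    Mono_Lymphoid = c("Mono", "Lymphoid"),
    Eos_Gran      = c("Eos", "Gran"),
    Bas_Gran      = c("Bas", "Gran"),
    Neu_total     = c("Neu", "total"),
    Gran_total    = c("Gran", "total"),
    Tcell_total   = c("Tcell", "total"),
    Bcell_total   = c("Bcell", "total"),
    NK_total      = c("NK", "total"),
    Mono_total    = c("Mono", "total"),
    Tcell_Bcell   = c("Tcell", "Bcell"))
}

check_base <- function(base, tol = 1e-6) {
  base <- unlist(base)[cell_types()]
  if (anyNA(base)) stop("Base proportions must cover all 12 cell types",
                        call. = FALSE)
  if (any(base < 0)) stop("Base proportions must be non-negative",
                          call. = FALSE)
  if (abs(sum(base) - 1) > tol) {
    stop(sprintf("Base proportions must sum to 1 (got %.8f); use the ",
                 sum(base)), "normalized deconvolution output", call. = FALSE)
  }
  base
}

#' Append the 7 hierarchical aggregates to 12 base proportions
#'
#' Bcell = Bnv + Bmem; CD4T = CD4nv + CD4mem + Treg; CD8T = CD8nv + CD8mem;
#' Tcell = CD4T + CD8T; Gran = Neu + Eos + Bas; Lymphoid = Tcell + Bcell +
#' NK; Myeloid = Gran + Mono. For normalized input Lymphoid + Myeloid = 1.
#'
#' @param base Named numeric vector of the 12 base proportions (normalized).
#' @return Named numeric vector of 19 proportions (12 base + 7 aggregates).
#' @export
#' @examples
#' aggregate_cell_types(setNames(rep(1 / 12, 12), cell_types()))
aggregate_cell_types <- function(base) {
  base <- check_base(base)
  aggs <- vapply(cell_type_branches(), function(members) sum(base[members]),
                 numeric(1))
  c(base, aggs)
}

#' Absolute cell counts from proportions and a leukocyte count
#'
#' Multiplies each of the 19 profile proportions by the total leukocyte
#' count, so component counts sum exactly to their aggregate counts.
#'
#' @param proportions Named 19-vector from [aggregate_cell_types()].
#' @param wbc_total Total leukocyte count (cells/uL), positive.
#' @return Named numeric vector of 19 counts (cells/uL).
#' @export
derive_cell_counts <- function(proportions, wbc_total) {
  if (!is.numeric(wbc_total) || is.na(wbc_total) || wbc_total <= 0) {
    stop("wbc_total must be a positive leukocyte count (cells/uL)",
         call. = FALSE)
  }
  stats::setNames(proportions[profile_proportion_names()] * wbc_total,
                  paste0(profile_proportion_names(), "_count"))
}

#' The 18 named immune-profile ratios
#'
#' Evaluates [profile_ratio_definitions()] on a 19-proportion profile.
#' Ratios with a zero denominator are undefined and reported as `NA`
#' (never infinity), keeping downstream tables finite.
#'
#' @param proportions Named 19-vector from [aggregate_cell_types()].
#' @return Named numeric vector of 18 ratios.
#' @export
derive_ratios <- function(proportions) {
  p <- c(proportions, total = sum(proportions[cell_types()]))
  eval_term <- function(term) {
    sum(p[strsplit(term, "+", fixed = TRUE)[[1]]])
  }
  vapply(profile_ratio_definitions(), function(def) {
    num <- eval_term(def[1]); den <- eval_term(def[2])
    if (den == 0) NA_real_ else num / den
  }, numeric(1))
}

#' Build the full immune profile for every deconvolved sample
#'
#' Derives, per sample, the 19 proportions (12 base cell types + 7
#' aggregates), the 18 named ratios, and -- when a total leukocyte count is
#' available -- the 19 absolute counts: 56 variables with counts, 37
#' without. Profiles are computed from the normalized proportions so the
#' count decomposition is exact. Samples whose deconvolution errored yield
#' all-`NA` rows.
#'
#' @param deconv A `deconv_result` from [deconvolve_matrix()], or a samples
#'   x 12 matrix of normalized proportions.
#' @param wbc Optional named numeric vector of total leukocyte counts
#'   (cells/uL) per sample, or a single value recycled to all samples.
#' @return Tibble, one row per sample: `sample_id`, 19 proportion columns,
#'   19 `_count` columns (only with `wbc`), 18 ratio columns.
#' @export
build_full_profile <- function(deconv, wbc = NULL) {
  props <- if (inherits(deconv, "deconv_result")) deconv$normalized
           else as.matrix(deconv)
  samples <- rownames(props)
  if (!is.null(wbc) && length(wbc) == 1 && is.null(names(wbc))) {
    wbc <- stats::setNames(rep(wbc, length(samples)), samples)
  }
  purrr::map_dfr(samples, function(s) {
    base <- props[s, ]
    if (anyNA(base)) {
      n_num <- 19 + 18 + if (!is.null(wbc)) 19 else 0
      row <- tibble::as_tibble_row(stats::setNames(
        as.list(rep(NA_real_, n_num)),
        c(profile_proportion_names(),
          if (!is.null(wbc)) paste0(profile_proportion_names(), "_count"),
          names(profile_ratio_definitions()))))
      return(tibble::add_column(row, sample_id = s, .before = 1))
    }
    p19 <- aggregate_cell_types(base)
    out <- as.list(p19)
    if (!is.null(wbc)) out <- c(out, as.list(derive_cell_counts(p19, wbc[[s]])))
    out <- c(out, as.list(derive_ratios(p19)))
    tibble::add_column(tibble::as_tibble_row(out), sample_id = s, .before = 1)
  })
}
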