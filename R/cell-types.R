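#' Canonical leukocyte cell types
#'
#' The twelve peripheral-blood leukocyte subtypes handled by this package, in
#' canonical column order: neutrophils (Neu), eosinophils (Eos), basophils
#' (Bas), monocytes (Mono), naive B cells (Bnv), memory B cells (Bmem),
#' naive CD4+ T cells (CD4nv), memory CD4+ T cells (CD4mem), regulatory T
#' cells (Treg), naive CD8+ T cells (CD8nv), memory CD8+ T cells (CD8mem),
#' and natural killer cells (NK). Every matrix of per-type values in the
#' package keeps its columns in this order.
#'
#' @return Character vector of the 12 canonical cell-type codes.
#' @export
#' @examples
#' cell_types()
cell_types <- function() {
  c("Neu", "Eos", "Bas", "Mono", "Bnv", "Bmem",
    "CD4nv", "CD4mem", "Treg", "CD8nv", "CD8mem", "NK")
}

#' Validate cell-type labels
#'
#' Checks labels against the canonical 12-code vocabulary and returns them
#' unchanged; unknown codes raise an error listing the accepted set, so typos
#' such as "CD4naive" are caught at parse time rather than deep in a fit.
#'
#' @param x Character vector of cell-type codes.
#' @return `x`, invisibly validated.
#' @export
validate_cell_types <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), cell_types())
  if (length(bad) > 0) {
    stop("Unknown cell-type code(s): ", paste(bad, collapse = ", "),
         ". Accepted codes: ", paste(cell_types(), collapse = ", "),
         call. = FALSE)
  }
  x
}

# Hierarchical branches used by the immune-profile layer. Each aggregate is
# the sum of its member base proportions; Lymphoid + Myeloid spans all 12.
cell_type_branches <- function() {
  list(
    Bcell    = c("Bnv", "Bmem"),
    CD4T     = c("CD4nv", "CD4mem", "Treg"),
    CD8T     = c("CD8nv", "CD8mem"),
    Tcell    = c("CD4nv", "CD4mem", "Treg", "CD8nv", "CD8mem"),
    Gran     = c("Neu", "Eos", "Bas"),
    Lymphoid = c("Bnv", "Bmem", "CD4nv", "CD4mem", "Treg",
                 "CD8nv", "CD8mem", "NK"),
    Myeloid  = c("Neu", "Eos", "Bas", "Mono")
  )
}
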