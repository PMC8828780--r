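# Probe exclusion rules defining the high-quality analysis set. The full
# pipeline order is: quality mask -> complete-case -> CpH -> chrX/chrY ->
# mask list. When a probe is excludable by several annotation rules it is
# attributed to the first applicable step; the final retained set does not
# depend on the order.

#' Mask low-quality beta entries
#'
#' Sets entry (i, j) missing when its out-of-band detection p-value exceeds
#' `p_threshold` (the signal cannot be distinguished from background) or its
#' bead count falls below `min_beads`. Already-missing entries stay missing;
#' all other entries are unchanged.
#'
#' @param beta A [beta_matrix()].
#' @param detp,beads Matrices aligned to `beta` (see [read_qc_matrices()]);
#'   either may be `NULL` to skip that rule.
#' @param p_threshold Detection p-value cutoff (default 0.05).
#' @param min_beads Minimum bead count (default 3).
#' @return The masked [beta_matrix()].
#' @export
apply_quality_mask <- function(beta, detp = NULL, beads = NULL,
                               p_threshold = 0.05, min_beads = 3) {
  vals <- unclass(beta)
  for (m in list(detp, beads)) {
    if (!is.null(m) && !identical(dim(m), dim(vals))) {
      stop("QC matrix not aligned to beta matrix", call. = FALSE)
    }
  }
  if (!is.null(detp)) vals[detp > p_threshold] <- NA_real_
  if (!is.null(beads)) vals[beads < min_beads] <- NA_real_
  beta_matrix(vals)
}

#' Keep only probes with complete data
#'
#' Retains exactly the probes observed in every sample, in their original
#' order. No imputation is performed: a masked signal may be cell-type
#' dependent, so filling it in would bias the reference means.
#'
#' @param beta A [beta_matrix()].
#' @return The complete-case [beta_matrix()].
#' @export
select_complete_probes <- function(beta) {
  keep <- rowSums(is.na(unclass(beta))) == 0
  if (!any(keep)) {
    stop(sprintf(
      "No probe has complete data (%d probes all carry missing entries)",
      nrow(beta)), call. = FALSE)
  }
  beta_matrix(unclass(beta)[keep, , drop = FALSE])
}

#' Remove CpH, sex-chromosome and masked probes
#'
#' Applies the annotation-based exclusions in fixed order: (1) non-CpG
#' (CpH) probes, which show minimal variation in blood; (2) chrX/chrY
#' probes, whose signal depends on sex-chromosome dosage; (3) probes on the
#' supplied mask list (known polymorphisms or cross-reactivity). Probes
#' missing from the annotation are dropped with a warning (manifests
#' version-drift), unless coverage falls below `min_annotated` of the input,
#' which is an error.
#'
#' @param beta A [beta_matrix()].
#' @param annotation Tibble from [read_probe_annotation()].
#' @param mask Character vector of probe IDs to exclude (default none).
#' @param min_annotated Minimum fraction of probes that must be annotated
#'   (default 0.95).
#' @return List with `beta` (filtered [beta_matrix()]) and `report`, a
#'   tibble of per-step removal counts (steps: unannotated, CpH, XY, mask,
#'   retained) satisfying `sum(n) == nrow(input)`.
#' @export
filter_probes <- function(beta, annotation, mask = character(),
                          min_annotated = 0.95) {
  probes <- rownames(beta)
  ann <- annotation[match(probes, annotation$probe_id), ]
  annotated <- !is.na(ann$probe_id)
  if (mean(annotated) < min_annotated) {
    stop(sprintf("Only %.1f%% of probes annotated (floor %.0f%%)",
                 100 * mean(annotated), 100 * min_annotated), call. = FALSE)
  }
  if (any(!annotated)) {
    warning(sprintf("%d unannotated probe(s) dropped", sum(!annotated)))
  }
  step <- rep(NA_character_, length(probes))
  step[!annotated] <- "unannotated"
  is_cph <- annotated & ann$probe_class != "CpG"
  step[is.na(step) & is_cph] <- "CpH"
  is_xy <- annotated & ann$chromosome %in% c("chrX", "chrY")
  step[is.na(step) & is_xy] <- "XY"
  in_mask <- probes %in% mask
  step[is.na(step) & in_mask] <- "mask"
  keep <- is.na(step)

  counts <- c(sum(step %in% "unannotated"), sum(step %in% "CpH"),
              sum(step %in% "XY"), sum(step %in% "mask"), sum(keep))
  report <- tibble::tibble(
    step = c("unannotated", "CpH", "XY", "mask", "retained"),
    n = counts)
  list(beta = beta_matrix(unclass(beta)[keep, , drop = FALSE]),
       report = report)
}
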