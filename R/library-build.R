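new_deconv_library <- function(means, method = "manual", params = list(),
                               seed = NA_integer_) {
  means <- as.matrix(means)
  storage.mode(means) <- "double"
  # columns must be canonical codes in canonical order; a subset is allowed
  # so that restricted designs (e.g. two-type test instances) stay valid
  stopifnot(all(colnames(means) %in% cell_types()),
            identical(colnames(means),
                      intersect(cell_types(), colnames(means))))
  structure(
    list(probe_ids = rownames(means), means = means,
         provenance = list(method = method, params = params, seed = seed)),
    class = "deconv_library")
}

#' @export
print.deconv_library <- function(x, ...) {
  cat(sprintf("deconv_library (%s): %d probes x %d cell types\n",
              x$provenance$method, nrow(x$means), ncol(x$means)))
  invisible(x)
}

#' Long-format view of a deconvolution library
#'
#' @param x A `deconv_library`.
#' @param ... Unused.
#' @return Tibble with columns `probe_id`, `cell_type`, `mean_beta`.
#' @export
tidy.deconv_library <- function(x, ...) {
  tibble::as_tibble(x$means, rownames = "probe_id") %>%
    tidyr::pivot_longer(-"probe_id", names_to = "cell_type",
                        values_to = "mean_beta")
}

# Vectorised Welch t over probe rows: target-type samples vs all remaining
# samples pooled. Positive t = hypermethylated in the target type.
welch_rows <- function(x_target, x_rest) {
  n1 <- ncol(x_target); n2 <- ncol(x_rest)
  m1 <- rowMeans(x_target); m2 <- rowMeans(x_rest)
  v1 <- rowSums((x_target - m1)^2) / (n1 - 1)
  v2 <- rowSums((x_rest - m2)^2) / (n2 - 1)
  se <- sqrt(v1 / n1 + v2 / n2)
  t <- (m1 - m2) / se
  zero_var <- se == 0
  t[zero_var] <- 0
  list(t = unname(t), zero_variance = unname(zero_var),
       delta = unname(m1 - m2))
}

#' One-vs-rest Welch t-statistics for a cell type
#'
#' For every probe, compares mean methylation in the target cell type's
#' reference samples against all other reference samples pooled, using the
#' unequal-variance (Welch) two-sample t-statistic. Positive values mean the
#' probe is hypermethylated in the target type. Probes with zero variance in
#' both groups get t = 0 and are flagged.
#'
#' @param ref A [reference_set()] with complete data.
#' @param cell_type One canonical cell-type code.
#' @return Tibble with columns `probe_id`, `t`, `delta_beta` (target minus
#'   rest mean), `zero_variance`.
#' @export
one_vs_rest_tstats <- function(ref, cell_type) {
  validate_cell_types(cell_type)
  stopifnot(length(cell_type) == 1)
  in_type <- ref$labels == cell_type
  if (sum(in_type) < 2 || sum(!in_type) < 2) {
    stop(sprintf("Need >= 2 samples in '%s' and >= 2 in the rest", cell_type),
         call. = FALSE)
  }
  vals <- unclass(ref$betas)
  if (anyNA(vals)) {
    stop("Reference betas must be complete; run select_complete_probes()",
         call. = FALSE)
  }
  w <- welch_rows(vals[, in_type, drop = FALSE], vals[, !in_type, drop = FALSE])
  tibble::tibble(probe_id = rownames(vals), t = w$t, delta_beta = w$delta,
                 zero_variance = w$zero_variance)
}

# Top-n probe IDs per direction with deterministic lexicographic tie-break.
top_markers <- function(tstats, n_per_direction, min_delta = 0) {
  usable <- tstats[is.finite(tstats$t) & !tstats$zero_variance, ]
  if (min_delta > 0) usable <- usable[abs(usable$delta_beta) >= min_delta, ]
  if (nrow(usable) < 2 * n_per_direction) {
    stop(sprintf("Only %d usable probes; need %d", nrow(usable),
                 2 * n_per_direction), call. = FALSE)
  }
  ord_hyper <- order(-usable$t, usable$probe_id)
  ord_hypo <- order(usable$t, usable$probe_id)
  list(hyper = usable[ord_hyper[seq_len(n_per_direction)], ],
       hypo = usable[ord_hypo[seq_len(n_per_direction)], ])
}

#' Build the candidate marker pool for library optimization
#'
#' For each cell type, ranks probes by one-vs-rest Welch t-statistic and
#' keeps the `L/2` most hypermethylated (largest t) and `L/2` most
#' hypomethylated (smallest t) probes; the union over the 12 types,
#' deduplicated, forms the IDOL search space. `L = 150` by default.
#' Ties in t are broken by lexicographic probe ID so the pool is
#' deterministic and independent of sample order.
#'
#' @param ref A [reference_set()] with complete data.
#' @param L Markers retained per cell type (split evenly across the hyper
#'   and hypo directions); must be even.
#' @param min_delta Optional minimum absolute mean-beta difference for a
#'   probe to qualify as a marker (default 0 = off).
#' @return A `candidate_pool`: list with `L`, `markers` (tibble: `cell_type`,
#'   `probe_id`, `direction`, `t`, `delta_beta`) and `probes` (deduplicated
#'   union, sorted).
#' @export
build_candidate_pool <- function(ref, L = 150, min_delta = 0) {
  if (L < 2 || L %% 2 != 0) stop("L must be an even number >= 2", call. = FALSE)
  per_side <- L / 2
  markers <- purrr::map_dfr(
    intersect(cell_types(), unique(ref$labels)), function(ct) {
      tt <- one_vs_rest_tstats(ref, ct)
      picked <- tryCatch(top_markers(tt, per_side, min_delta),
        error = function(e) stop(sprintf("Cell type '%s': %s", ct,
                                         conditionMessage(e)), call. = FALSE))
      dplyr::bind_rows(
        dplyr::mutate(picked$hyper, direction = "hyper"),
        dplyr::mutate(picked$hypo, direction = "hypo")) %>%
        dplyr::mutate(cell_type = ct, .before = 1)
    })
  structure(
    list(L = L, markers = markers,
         probes = sort(unique(markers$probe_id))),
    class = "candidate_pool")
}

#' @export
print.candidate_pool <- function(x, ...) {
  cat(sprintf("candidate_pool: L = %d, %d marker picks, %d unique probes\n",
              x$L, nrow(x$markers), length(x$probes)))
  invisible(x)
}

#' Compute library mean-methylation columns from a reference set
#'
#' For each requested probe, averages beta values over the reference samples
#' of each cell type, yielding the probes x 12 design matrix used by the
#' constrained-projection solver. Input probe order is preserved. A cell
#' type represented by a single sample contributes that sample's value with
#' a warning.
#'
#' @param ref A [reference_set()] with complete data.
#' @param probes Character vector of probe IDs (subset of the reference).
#' @param method,params,seed Provenance recorded in the library.
#' @return A `deconv_library`.
#' @export
assemble_library <- function(ref, probes, method = "manual",
                             params = list(), seed = NA_integer_) {
  unknown <- setdiff(probes, rownames(ref$betas))
  if (length(unknown) > 0) {
    stop("Probe(s) absent from the reference: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  if (length(ref$underpowered) > 0) {
    warning("Single-sample cell type(s): ",
            paste(ref$underpowered, collapse = ", "),
            "; library means equal that sample's values")
  }
  vals <- unclass(ref$betas)[probes, , drop = FALSE]
  present <- intersect(cell_types(), unique(ref$labels))
  type <- factor(ref$labels, levels = present)
  means <- vapply(present, function(ct) {
    rowMeans(vals[, type == ct, drop = FALSE])
  }, numeric(length(probes)))
  if (length(probes) == 1) {
    means <- matrix(means, nrow = 1, dimnames = list(probes, present))
  }
  new_deconv_library(means, method = method, params = params, seed = seed)
}

#' Automatic marker-library selection (top-N per direction)
#'
#' The automatic ("pickCompProbes"-style) library: for each of the 12 cell
#' types take the `n_per_direction` most hypermethylated and the
#' `n_per_direction` most hypomethylated probes by one-vs-rest t-statistic,
#' pool and deduplicate, and average the reference betas per type. With the
#' default of 50 probes per direction and no cross-type collisions this
#' yields a 1200-probe library.
#'
#' @inheritParams build_candidate_pool
#' @param n_per_direction Markers per cell type per direction (default 50).
#' @return A `deconv_library` with method tag `"auto"`.
#' @export
auto_select_library <- function(ref, n_per_direction = 50, min_delta = 0) {
  pool <- build_candidate_pool(ref, L = 2 * n_per_direction,
                               min_delta = min_delta)
  n_picks <- nrow(pool$markers)
  n_unique <- length(pool$probes)
  if (n_unique < n_picks) {
    message(sprintf("%d marker picks collide across cell types",
                    n_picks - n_unique))
  }
  lib <- assemble_library(ref, pool$probes, method = "auto",
                          params = list(n_per_direction = n_per_direction))
  lib
}

#' Genomic-context composition and enrichment of a library
#'
#' Tabulates the library probes over island context, functional context and
#' regulatory flags, and tests each category for enrichment relative to a
#' background probe set with Fisher's exact test (odds ratio of category
#' membership, library vs background-minus-library, with 95% CI).
#'
#' @param lib A `deconv_library`.
#' @param annotation Tibble from [read_probe_annotation()] covering all
#'   library and background probes.
#' @param background Character vector of background probe IDs (e.g. the
#'   post-filter analysis set).
#' @return Tibble with columns `group`, `category`, `n`, `pct`,
#'   `odds_ratio`, `ci_lo`, `ci_hi`, `p_value`.
#' @export
summarize_library_context <- function(lib, annotation, background) {
  if (length(background) == 0) stop("Empty background set", call. = FALSE)
  background <- union(background, lib$probe_ids)
  ann <- annotation[match(background, annotation$probe_id), ]
  if (anyNA(ann$probe_id)) {
    stop("All library and background probes must be annotated", call. = FALSE)
  }
  in_lib <- background %in% lib$probe_ids
  n_lib <- sum(in_lib)

  one_category <- function(member, group, category) {
    tab <- matrix(c(sum(member & in_lib), sum(!member & in_lib),
                    sum(member & !in_lib), sum(!member & !in_lib)), 2, 2)
    ft <- stats::fisher.test(tab)
    tibble::tibble(group = group, category = category,
                   n = sum(member & in_lib),
                   pct = 100 * sum(member & in_lib) / n_lib,
                   odds_ratio = unname(ft$estimate),
                   ci_lo = ft$conf.int[1], ci_hi = ft$conf.int[2],
                   p_value = ft$p.value)
  }

  rows <- purrr::map_dfr(
    c("Island", "Shore", "Shelf", "OpenSea"),
    function(ctx) one_category(ann$island_context == ctx, "island_context", ctx))
  if ("functional_context" %in% names(ann) &&
      !all(is.na(ann$functional_context))) {
    rows <- dplyr::bind_rows(rows, purrr::map_dfr(
      c("Promoter", "Exon", "Intron", "Intergenic"),
      function(ctx) one_category(!is.na(ann$functional_context) &
                                   ann$functional_context == ctx,
                                 "functional_context", ctx)))
  }
  if ("flags" %in% names(ann) && !all(is.na(ann$flags))) {
    flag_str <- ifelse(is.na(ann$flags), "", ann$flags)
    rows <- dplyr::bind_rows(rows, purrr::map_dfr(
      c("Enhancer", "DHS", "OpenChromatin", "TFBS"),
      function(fl) one_category(
        vapply(strsplit(flag_str, ",", fixed = TRUE),
               function(v) fl %in% trimws(v), logical(1)), "flag", fl)))
  }
  rows
}
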