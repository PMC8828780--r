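# Readers and writers for the on-disk artifacts. TSV is the canonical
# format (series-matrix style exports are tab-delimited); CSV is accepted on
# read by sniffing the delimiter of the first non-comment line. Missing
# values may be written "", "NA" or "NaN" and are always written back "NA".

sniff_delim <- function(path) {
  first <- readLines(path, n = 50L)
  first <- first[!startsWith(first, "#")]
  if (length(first) == 0) return("\t")
  if (sum(gregexpr("\t", first[1], fixed = TRUE)[[1]] > 0) > 0) "\t" else ","
}

read_delim_quiet <- function(path, ...) {
  readr::read_delim(path, delim = sniff_delim(path), comment = "#",
                    na = c("", "NA", "NaN"), show_col_types = FALSE,
                    progress = FALSE, ...)
}

#' Read a beta-value matrix from delimited text
#'
#' Expects a header row of sample IDs and a first column of probe IDs;
#' TSV or CSV, plain or gzip-compressed. Values must be numeric in [0, 1];
#' empty cells, `NA` and `NaN` denote missing. Duplicate probe or sample IDs
#' and out-of-range values are format errors naming the offender.
#'
#' @param path File path.
#' @return A [beta_matrix()].
#' @export
read_beta_matrix <- function(path) {
  df <- read_delim_quiet(path, col_types = readr::cols(
    .default = readr::col_character()))
  probe_ids <- df[[1]]
  vals <- as.data.frame(df[-1])
  num <- suppressWarnings(vapply(vals, as.numeric, numeric(nrow(vals))))
  if (nrow(vals) == 1) num <- matrix(num, nrow = 1)
  bad <- which(is.na(num) & !is.na(as.matrix(vals)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("Non-numeric beta value at probe '%s', sample '%s': '%s'",
                 probe_ids[bad[1, 1]], colnames(vals)[bad[1, 2]],
                 vals[bad[1, 1], bad[1, 2]]), call. = FALSE)
  }
  beta_matrix(num, probe_ids = probe_ids, sample_ids = colnames(vals))
}

#' Write a beta-value matrix as TSV
#'
#' Deterministic output: probes in stored order, values at 6 decimal places,
#' missing entries written `NA`. [read_beta_matrix()] round-trips the file.
#'
#' @param beta A [beta_matrix()].
#' @param path Output path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path) {
  df <- tibble::as_tibble(formatC(unclass(beta), format = "f", digits = 6))
  df[is.na(unclass(beta))] <- NA_character_
  df <- tibble::add_column(df, probe_id = rownames(beta), .before = 1)
  readr::write_tsv(df, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read detection p-value and bead-count matrices aligned to a beta matrix
#'
#' Both files follow the beta-matrix layout. The matrices must cover exactly
#' the probes and samples of `beta`; any discrepancy is an alignment error
#' reporting the symmetric difference of identifiers. Bead counts must be
#' non-negative integers; detection p-values must lie in [0, 1].
#'
#' @param detp_path,beads_path Paths; either may be `NULL` to skip that
#'   matrix.
#' @param beta The [beta_matrix()] the QC matrices describe.
#' @return List with elements `detp` and `beads` (numeric matrices aligned
#'   to `beta`, or `NULL`).
#' @export
read_qc_matrices <- function(detp_path = NULL, beads_path = NULL, beta) {
  read_aligned <- function(path, what) {
    df <- read_delim_quiet(path)
    m <- as.matrix(df[-1])
    rownames(m) <- as.character(df[[1]])
    extra <- setdiff(rownames(m), rownames(beta))
    miss <- setdiff(rownames(beta), rownames(m))
    extra_s <- setdiff(colnames(m), colnames(beta))
    miss_s <- setdiff(colnames(beta), colnames(m))
    if (length(c(extra, miss, extra_s, miss_s)) > 0) {
      stop(sprintf(
        "%s matrix misaligned with beta matrix; ID difference: %s", what,
        paste(utils::head(c(extra, miss, extra_s, miss_s), 10),
              collapse = ", ")), call. = FALSE)
    }
    m[rownames(beta), colnames(beta), drop = FALSE]
  }
  detp <- beads <- NULL
  if (!is.null(detp_path)) {
    detp <- read_aligned(detp_path, "Detection p-value")
    if (any(detp < 0 | detp > 1, na.rm = TRUE)) {
      stop("Detection p-values must lie in [0, 1]", call. = FALSE)
    }
  }
  if (!is.null(beads_path)) {
    beads <- read_aligned(beads_path, "Bead-count")
    if (any(beads < 0, na.rm = TRUE)) {
      stop("Bead counts must be non-negative", call. = FALSE)
    }
  }
  list(detp = detp, beads = beads)
}

#' Read a probe annotation table
#'
#' Columns: `probe_id`, `chromosome` ("chr"-prefixed or bare; bare tokens
#' are normalized to "chr" form on read), `probe_class` (CpG, CpH or
#' SNP-control), `island_context` (Island, Shore, Shelf, OpenSea), and
#' optionally `functional_context` (Promoter, Exon, Intron, Intergenic) and
#' `flags` (comma-separated subset of Enhancer, DHS, OpenChromatin, TFBS).
#'
#' @param path File path.
#' @return Tibble with the validated columns above.
#' @export
read_probe_annotation <- function(path) {
  ann <- read_delim_quiet(path)
  names(ann) <- tolower(names(ann))
  required <- c("probe_id", "chromosome", "probe_class", "island_context")
  if (!all(required %in% names(ann))) {
    stop("Probe annotation needs columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(ann$probe_id)) {
    stop("Duplicate probe IDs in annotation", call. = FALSE)
  }
  chrom <- as.character(ann$chromosome)
  bare <- !startsWith(chrom, "chr")
  chrom[bare] <- paste0("chr", chrom[bare])
  ok_chrom <- c(paste0("chr", 1:22), "chrX", "chrY")
  bad <- setdiff(unique(chrom), ok_chrom)
  if (length(bad) > 0) {
    stop("Unknown chromosome token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ann$chromosome <- chrom
  bad_class <- setdiff(unique(ann$probe_class), c("CpG", "CpH", "SNP-control"))
  if (length(bad_class) > 0) {
    stop("Unknown probe class: ", paste(bad_class, collapse = ", "),
         call. = FALSE)
  }
  bad_ctx <- setdiff(unique(ann$island_context),
                     c("Island", "Shore", "Shelf", "OpenSea"))
  if (length(bad_ctx) > 0) {
    stop("Unknown island context: ", paste(bad_ctx, collapse = ", "),
         call. = FALSE)
  }
  if ("functional_context" %in% names(ann)) {
    bad_fun <- setdiff(stats::na.omit(unique(ann$functional_context)),
                       c("Promoter", "Exon", "Intron", "Intergenic"))
    if (length(bad_fun) > 0) {
      stop("Unknown functional context: ", paste(bad_fun, collapse = ", "),
           call. = FALSE)
    }
  }
  if ("flags" %in% names(ann)) {
    toks <- unique(unlist(strsplit(stats::na.omit(ann$flags), ",", fixed = TRUE)))
    bad_flag <- setdiff(trimws(toks),
                        c("Enhancer", "DHS", "OpenChromatin", "TFBS", ""))
    if (length(bad_flag) > 0) {
      stop("Unknown annotation flag: ", paste(bad_flag, collapse = ", "),
           call. = FALSE)
    }
  }
  tibble::as_tibble(ann)
}

#' Read a probe mask list
#'
#' One probe ID per line; blank lines and `#` comments are skipped. Used for
#' the polymorphic / cross-reactive probe exclusion step.
#'
#' @param path File path.
#' @return Character vector of unique probe IDs.
#' @export
read_mask_list <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(lines)
}

#' Read a sample sheet
#'
#' Columns: `sample_id`, optionally `cell_type` (validated against the 12
#' canonical codes) and `wbc_total` (total leukocyte count, cells/uL).
#'
#' @param path File path.
#' @return Tibble with the validated columns.
#' @export
read_sample_sheet <- function(path) {
  sheet <- read_delim_quiet(path)
  names(sheet) <- tolower(names(sheet))
  if (!"sample_id" %in% names(sheet)) {
    stop("Sample sheet needs a sample_id column", call. = FALSE)
  }
  if (anyDuplicated(sheet$sample_id)) {
    stop("Duplicate sample IDs in sample sheet", call. = FALSE)
  }
  if ("cell_type" %in% names(sheet)) {
    validate_cell_types(stats::na.omit(sheet$cell_type))
  }
  if ("wbc_total" %in% names(sheet) &&
      any(sheet$wbc_total <= 0, na.rm = TRUE)) {
    stop("wbc_total must be positive (cells/uL)", call. = FALSE)
  }
  tibble::as_tibble(sheet)
}

#' Write / read a deconvolution library
#'
#' The on-disk form is a TSV whose payload has a `probe_id` column followed
#' by one mean-beta column per cell type in canonical order, preceded by
#' `#`-prefixed metadata lines recording the construction method, its
#' parameters and the seed, so the payload stays loadable by generic table
#' readers. `read_library(write_library(lib))` reproduces the library to six
#' decimal places. Mean betas marginally outside [0, 1] (within 1e-6, e.g.
#' from decimal formatting) are clipped on read with a warning; larger
#' violations are format errors.
#'
#' @param lib A `deconv_library` from [assemble_library()].
#' @param path File path.
#' @return `write_library` returns `path` invisibly; `read_library` returns
#'   the `deconv_library`.
#' @export
write_library <- function(lib, path) {
  prov <- lib$provenance
  meta <- c(
    sprintf("# deconv_library method=%s", prov$method %||% "manual"),
    sprintf("# params=%s",
            paste(names(prov$params), unlist(prov$params),
                  sep = "=", collapse = ";")),
    sprintf("# seed=%s", prov$seed %||% "NA"),
    sprintf("# n_probes=%d", nrow(lib$means)))
  writeLines(meta, path)
  df <- tibble::as_tibble(formatC(lib$means, format = "f", digits = 6))
  df <- tibble::add_column(df, probe_id = rownames(lib$means), .before = 1)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  df <- read_delim_quiet(path)
  if (!setequal(setdiff(names(df), "probe_id"), cell_types())) {
    missing_ct <- setdiff(cell_types(), names(df))
    stop("Library file does not carry the 12 canonical cell-type columns",
         if (length(missing_ct) > 0)
           paste0(" (missing: ", paste(missing_ct, collapse = ", "), ")"),
         call. = FALSE)
  }
  m <- as.matrix(df[cell_types()])
  rownames(m) <- df$probe_id
  out_of_range <- abs(pmin(pmax(m, 0), 1) - m)
  if (any(out_of_range > 1e-6, na.rm = TRUE)) {
    stop("Library mean betas outside [0, 1]", call. = FALSE)
  }
  if (any(out_of_range > 0, na.rm = TRUE)) {
    warning("Mean betas marginally outside [0, 1] clipped on read")
    m <- pmin(pmax(m, 0), 1)
  }
  method <- sub("^# deconv_library method=", "",
                grep("^# deconv_library method=", meta, value = TRUE)[1])
  seed_line <- sub("^# seed=", "", grep("^# seed=", meta, value = TRUE)[1])
  new_deconv_library(m, method = method %||% "manual",
                     seed = suppressWarnings(as.integer(seed_line)))
}

#' Write an immune-profile table
#'
#' One row per sample; columns in fixed order: `sample_id`, the 19
#' proportions (12 base types then 7 aggregates), the 19 absolute counts
#' (suffix `_count`, present only when counts were derived), then the 18
#' named ratios. Undefined ratios are written `NA`. A `#` header line
#' documents whether counts are included.
#'
#' @param profiles Tibble from [build_full_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(profiles, path) {
  has_counts <- any(endsWith(names(profiles), "_count"))
  writeLines(sprintf("# immune_profile counts=%s",
                     if (has_counts) "included" else "omitted (no wbc_total)"),
             path)
  readr::write_tsv(profiles, path, na = "NA", append = TRUE,
                   col_names = TRUE, progress = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || all(is.na(a))) b else a
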