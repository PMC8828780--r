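# Synthetic reference panels and Dirichlet artificial mixtures with ground
# truth. The generator plants, per cell type, hypo- and hypermethylated
# marker CpGs on a background methylome shared across types, draws sorted
# reference samples with residual impurity (one random contaminating type),
# and builds mixtures y = M w + noise from Dirichlet-distributed w.

#' Simulation configuration
#'
#' Defaults emulate the design of a 56-sample sorted-leukocyte reference
#' panel with 24 Dirichlet artificial mixtures: per-type sample counts
#' (6, 4, 6, 5, 4, 6, 5, 4, 3, 5, 4, 4) for Neu...NK, sorted-cell purity
#' between 85% and 99%, and a Dirichlet concentration weighted toward
#' neutrophils and CD4 T cells so draws resemble adult blood.
#'
#' @param markers_per_type Planted markers per cell type per direction
#'   (hypo and hyper), default 20.
#' @param n_background_probes Non-marker probes sharing one beta across all
#'   types, default 1000.
#' @param n_noise_probes Pure-noise probes (default 0): their expected beta
#'   is shared by all types, but every measurement -- reference sample or
#'   mixture -- gets independent Gaussian noise of sd `noise_probe_sd`,
#'   emulating CpGs with high cell-type-independent variability. Unlike the
#'   quiet background probes these actively distort deconvolution fits, so
#'   they are the dilution used in marker-importance experiments.
#' @param noise_probe_sd Per-measurement sd of the pure-noise probes
#'   (default 0.2).
#' @param n_samples_per_type Integer vector of reference samples per cell
#'   type, in canonical order.
#' @param noise_sd Gaussian beta-scale noise sd added to reference samples
#'   and mixtures (clipped to [0, 1]), default 0.01.
#' @param purity_range Sorted-cell purity range `c(lo, hi)`; each reference
#'   sample's purity is drawn uniformly in it. Default `c(0.85, 0.99)`.
#' @param dirichlet_alpha Positive 12-vector of Dirichlet concentration
#'   parameters for mixture proportions.
#' @param n_mixtures Number of artificial mixtures, default 24.
#' @param seed Integer seed; `simulate_reference()` uses `seed` and
#'   [simulate_mixtures()] uses `seed + 1` so the two stages have disjoint
#'   but reproducible streams.
#' @return A `sim_config` list.
#' @export
sim_config <- function(markers_per_type = 20,
                       n_background_probes = 1000,
                       n_noise_probes = 0,
                       noise_probe_sd = 0.2,
                       n_samples_per_type = c(6, 4, 6, 5, 4, 6,
                                              5, 4, 3, 5, 4, 4),
                       noise_sd = 0.01,
                       purity_range = c(0.85, 0.99),
                       dirichlet_alpha = c(Neu = 15, Eos = 1, Bas = 0.3,
                                           Mono = 2.5, Bnv = 0.7, Bmem = 0.7,
                                           CD4nv = 2, CD4mem = 2, Treg = 0.7,
                                           CD8nv = 1.2, CD8mem = 1.5,
                                           NK = 1.5),
                       n_mixtures = 24,
                       seed = 1L) {
  stopifnot(markers_per_type >= 1, n_background_probes >= 0,
            n_noise_probes >= 0, noise_probe_sd >= 0,
            length(n_samples_per_type) == 12, all(n_samples_per_type >= 1),
            noise_sd >= 0, length(purity_range) == 2,
            purity_range[1] > 0, purity_range[1] <= purity_range[2],
            purity_range[2] <= 1, length(dirichlet_alpha) == 12,
            all(dirichlet_alpha > 0), n_mixtures >= 1)
  structure(list(markers_per_type = markers_per_type,
                 n_background_probes = n_background_probes,
                 n_noise_probes = n_noise_probes,
                 noise_probe_sd = noise_probe_sd,
                 n_samples_per_type = n_samples_per_type,
                 noise_sd = noise_sd, purity_range = purity_range,
                 dirichlet_alpha = stats::setNames(dirichlet_alpha,
                                                   cell_types()),
                 n_mixtures = n_mixtures, seed = as.integer(seed)),
            class = "sim_config")
}

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  sw <- g / rowSums(g)
  colnames(sw) <- names(alpha)
  sw
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Simulate a sorted-cell reference panel
#'
#' Builds the true per-type methylome matrix: for each cell type,
#' `markers_per_type` hypomethylated markers (own-type beta uniform in
#' [0, 0.15], other types in [0.7, 1]) and as many hypermethylated markers
#' (the ranges reversed); background probes carry one beta per probe, drawn
#' from a bimodal Beta(0.4, 0.4), shared by all types. Each reference sample
#' mixes its own type's methylome with a single random other type at
#' `1 - purity` (the hardest contamination pattern for the purity screen),
#' adds truncated Gaussian noise, and clips to [0, 1].
#'
#' @param config A [sim_config()].
#' @return List with `reference` (a [reference_set()] whose `purity` holds
#'   the true drawn purities), `marker_map` (tibble: `probe_id`,
#'   `cell_type`, `direction`), `methylomes` (probes x 12 true methylome
#'   matrix) and `contaminants` (tibble: `sample_id`, `contaminant`).
#' @export
simulate_reference <- function(config = sim_config()) {
  set.seed(config$seed)
  m <- config$markers_per_type
  types <- cell_types()
  K <- length(types)

  marker_map <- purrr::map_dfr(types, function(ct) {
    tibble::tibble(
      probe_id = sprintf("cg_%s_%s_%03d", ct,
                         rep(c("hypo", "hyper"), each = m),
                         rep(seq_len(m), 2)),
      cell_type = ct,
      direction = rep(c("hypo", "hyper"), each = m))
  })
  n_bg <- config$n_background_probes
  bg_ids <- if (n_bg > 0) sprintf("cg_bg_%05d", seq_len(n_bg)) else character()
  n_np <- config$n_noise_probes
  noise_ids <- if (n_np > 0) sprintf("cg_noise_%05d", seq_len(n_np)) else character()
  probes <- c(marker_map$probe_id, bg_ids, noise_ids)

  M <- matrix(NA_real_, length(probes), K, dimnames = list(probes, types))
  for (ct in types) {
    hypo <- marker_map$probe_id[marker_map$cell_type == ct &
                                  marker_map$direction == "hypo"]
    hyper <- marker_map$probe_id[marker_map$cell_type == ct &
                                   marker_map$direction == "hyper"]
    M[hypo, ct] <- stats::runif(m, 0.00, 0.15)
    M[hypo, setdiff(types, ct)] <- ifelse(
      is.na(M[hypo, setdiff(types, ct)]),
      stats::runif(m * (K - 1), 0.70, 1.00), M[hypo, setdiff(types, ct)])
    M[hyper, ct] <- stats::runif(m, 0.70, 1.00)
    M[hyper, setdiff(types, ct)] <- ifelse(
      is.na(M[hyper, setdiff(types, ct)]),
      stats::runif(m * (K - 1), 0.00, 0.15), M[hyper, setdiff(types, ct)])
  }
  if (n_bg > 0) {
    M[bg_ids, ] <- matrix(rep(stats::rbeta(n_bg, 0.4, 0.4), K), n_bg, K)
  }
  if (n_np > 0) {
    M[noise_ids, ] <- matrix(rep(stats::rbeta(n_np, 2, 2), K), n_np, K)
  }

  n_per <- stats::setNames(config$n_samples_per_type, types)
  sample_ids <- unlist(purrr::map(types, function(ct)
    sprintf("%s_%d", ct, seq_len(n_per[[ct]]))))
  labels <- stats::setNames(rep(types, n_per), sample_ids)
  purity <- stats::setNames(
    stats::runif(length(sample_ids), config$purity_range[1],
                 config$purity_range[2]), sample_ids)
  contaminant <- stats::setNames(vapply(labels, function(ct)
    sample(setdiff(types, ct), 1), character(1)), sample_ids)

  vals <- vapply(sample_ids, function(s) {
    pure <- M[, labels[[s]]]
    cont <- M[, contaminant[[s]]]
    y <- purity[[s]] * pure + (1 - purity[[s]]) * cont
    if (config$noise_sd > 0) {
      y <- y + stats::rnorm(length(y), sd = config$noise_sd)
    }
    if (n_np > 0) {
      y[noise_ids] <- y[noise_ids] +
        stats::rnorm(n_np, sd = config$noise_probe_sd)
    }
    clip01(y)
  }, numeric(length(probes)))
  rownames(vals) <- probes
  attr(M, "noise_probes") <- noise_ids

  list(reference = reference_set(beta_matrix(vals), labels, purity = purity),
       marker_map = marker_map,
       methylomes = M,
       contaminants = tibble::tibble(sample_id = sample_ids,
                                     contaminant = unname(contaminant)))
}

#' Simulate Dirichlet artificial mixtures with known composition
#'
#' Draws mixture proportions from a twelve-component Dirichlet, forms each
#' mixture's beta vector as the proportion-weighted combination of the true
#' per-type methylomes, adds truncated Gaussian noise, and clips to [0, 1].
#' The returned truth rows sum to one exactly.
#'
#' @param methylomes Probes x 12 true methylome matrix from
#'   [simulate_reference()].
#' @param config A [sim_config()] (`n_mixtures`, `dirichlet_alpha`,
#'   `noise_sd`, `seed + 1` are used).
#' @param prefix Sample-ID prefix, default `"mix"`.
#' @return List with `mixtures` (a [beta_matrix()]) and `truth`
#'   (a [mixture_truth()]).
#' @export
simulate_mixtures <- function(methylomes, config = sim_config(),
                              prefix = "mix") {
  set.seed(config$seed + 1L)
  n <- config$n_mixtures
  w <- rdirichlet(n, config$dirichlet_alpha[cell_types()])
  rownames(w) <- sprintf("%s_%02d", prefix, seq_len(n))
  Y <- methylomes %*% t(w)
  if (config$noise_sd > 0) {
    Y <- Y + stats::rnorm(length(Y), sd = config$noise_sd)
  }
  noise_ids <- intersect(attr(methylomes, "noise_probes"), rownames(Y))
  if (length(noise_ids) > 0 && config$noise_probe_sd > 0) {
    Y[noise_ids, ] <- Y[noise_ids, ] +
      stats::rnorm(length(noise_ids) * n, sd = config$noise_probe_sd)
  }
  Y <- clip01(Y)
  list(mixtures = beta_matrix(Y), truth = mixture_truth(w))
}

#' Named desk-scale study scenarios
#'
#' Deterministic fixtures mirroring a training/testing/validation layout of
#' artificial-mixture experiments: `"train6"` and `"test6"` are six-mixture
#' sets drawn from the same reference panel under different mixture seeds,
#' `"validate12"` is a 12-mixture set built on an independently simulated
#' reference (as if from separately isolated cells), and `"full24"` is the
#' full 24-mixture set on the main panel. All scenarios use the default
#' [sim_config()] panel layout and fixed documented seeds (reference 100,
#' mixtures 100/200/300/400; the independent validation panel uses 500).
#'
#' @param name One of `"train6"`, `"test6"`, `"validate12"`, `"full24"`.
#' @return List with `reference`, `marker_map`, `methylomes`, `mixtures`,
#'   `truth`, and `pool` (a `candidate_pool` at L = 150 on the scenario's
#'   reference).
#' @export
mixture_scenario <- function(name = c("train6", "test6", "validate12",
                                      "full24")) {
  name <- tryCatch(match.arg(name), error = function(e)
    stop("Unknown scenario '", name[1],
         "'; options: train6, test6, validate12, full24", call. = FALSE))
  spec <- switch(name,
    train6     = list(n = 6L, ref_seed = 100L, mix_seed = 100L),
    test6      = list(n = 6L, ref_seed = 100L, mix_seed = 200L),
    validate12 = list(n = 12L, ref_seed = 500L, mix_seed = 300L),
    full24     = list(n = 24L, ref_seed = 100L, mix_seed = 400L))
  ref_cfg <- sim_config(seed = spec$ref_seed)
  sim <- simulate_reference(ref_cfg)
  mix_cfg <- sim_config(n_mixtures = spec$n, seed = spec$mix_seed)
  mix <- simulate_mixtures(sim$methylomes, mix_cfg, prefix = name)
  pool <- build_candidate_pool(sim$reference, L = 150)
  c(sim, mix, list(pool = pool))
}
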