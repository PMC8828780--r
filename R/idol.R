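# IDOL (IDentifying Optimal Libraries): iteratively resample candidate
# libraries from a marker pool, score each against training mixtures of
# known composition, measure every sampled CpG's leave-one-out impact on
# the mean RMSE, and raise or lower each CpG's inclusion probability
# accordingly. The best-scoring library seen across iterations is returned.

#' IDOL configuration
#'
#' @param library_size Library size S drawn at each iteration.
#' @param n_iterations Number of iterations (default 500).
#' @param size_grid Library sizes for [run_idol_grid()]; default 250 to 1100
#'   in steps of 50, 1200 to 2000 in steps of 100, then 2500 and 3000.
#' @param seed Integer seed for reproducibility (`NULL` = leave the RNG
#'   stream alone).
#' @param eta Multiplicative probability update rate in (0, 1); a sampled
#'   CpG's weight is multiplied by `1 + eta` when removing it hurts accuracy
#'   and by `1 - eta` otherwise (default 0.05).
#' @param p_min Probability floor keeping every pool CpG reachable
#'   (default 0.01).
#' @param impact_tol Minimum leave-one-out RMSE increase (percentage
#'   points) for a CpG to count as beneficial (default 0). A small positive
#'   value filters out sign noise from the quadratic-programming fits;
#'   useful together with a large `eta` in short runs.
#'
#' @details `eta = 0.05` is sized for runs of several hundred iterations,
#' where each pool CpG is resampled often enough for its weight to traverse
#' the whole `[p_min, 1]` range. For short exploratory runs scale `eta` up
#' roughly in inverse proportion to the iteration budget (e.g. `eta = 0.5`
#' at 50 iterations) or the weights cannot concentrate before the run ends.
#'
#' @return An `idol_config` list.
#' @export
idol_config <- function(library_size = 300, n_iterations = 500,
                        size_grid = c(seq(250, 1100, by = 50),
                                      seq(1200, 2000, by = 100), 2500, 3000),
                        seed = NULL, eta = 0.05, p_min = 0.01,
                        impact_tol = 0) {
  stopifnot(library_size >= 1, n_iterations >= 1,
            eta > 0, eta < 1, p_min > 0, p_min <= 1, impact_tol >= 0)
  structure(list(library_size = library_size, n_iterations = n_iterations,
                 size_grid = size_grid, seed = seed, eta = eta,
                 p_min = p_min, impact_tol = impact_tol),
            class = "idol_config")
}

#' Draw a candidate library by weighted sampling
#'
#' Samples exactly `S` distinct probes from the pool, without replacement,
#' with per-draw probability proportional to the current inclusion weights
#' (successive draws from the renormalized weight vector, i.e.
#' `sample(prob = )` semantics, so runs are reproducible given the seed).
#'
#' @param weights Named numeric vector of inclusion weights over the pool.
#' @param S Library size.
#' @return Character vector of `S` probe IDs.
#' @export
sample_candidate_library <- function(weights, S) {
  if (S > length(weights)) {
    stop(sprintf("Requested size %d exceeds pool size %d", S, length(weights)),
         call. = FALSE)
  }
  sample(names(weights), S, replace = FALSE, prob = weights)
}

# Internal scorer used by the optimizer: QP-deconvolve every mixture with
# the probes x 12 mean matrix and return mean RMSE (pp) and mean R^2 on the
# normalized estimates. Crossproducts are passed so leave-one-out scoring
# can downdate them in O(K^2) per probe.
score_cross <- function(XtX, XtY, truth) {
  n <- ncol(XtY)
  K <- ncol(XtX)
  est <- matrix(0, n, K)
  for (j in seq_len(n)) {
    w <- cpqp_solve_cross(XtX, XtY[, j])
    s <- sum(w)
    est[j, ] <- if (s > 0) w / s else NA_real_
  }
  d <- est - truth
  rmse <- 100 * sqrt(colMeans(d^2))
  r2 <- vapply(seq_len(K), function(k) {
    if (stats::sd(truth[, k]) == 0 || anyNA(est[, k]) ||
        stats::sd(est[, k]) == 0) return(NA_real_)
    stats::cor(est[, k], truth[, k])^2
  }, numeric(1))
  c(mean_rmse = mean(rmse), mean_r2 = mean(r2, na.rm = TRUE))
}

# Shared setup: align mixtures/truth to the pool and check completeness.
idol_inputs <- function(pool_probes, ref, mixtures, truth) {
  missing_probes <- setdiff(pool_probes, rownames(mixtures))
  if (length(missing_probes) > 0) {
    stop("Pool probe(s) absent from the mixtures: ",
         paste(utils::head(missing_probes, 5), collapse = ", "), call. = FALSE)
  }
  Y <- unclass(mixtures)[pool_probes, , drop = FALSE]
  if (anyNA(Y)) {
    stop("Training mixtures must be complete over the pool probes",
         call. = FALSE)
  }
  tr <- unclass(truth)[colnames(Y), , drop = FALSE]
  lib_all <- assemble_library(ref, pool_probes, method = "idol-pool")
  list(Y = Y, truth = tr, means = lib_all$means)
}

#' Score a candidate library against training mixtures
#'
#' Assembles the library means from the reference, deconvolves every
#' training mixture by constrained projection, and evaluates the estimates
#' against the known proportions.
#'
#' @param probes Character vector of library probe IDs.
#' @param ref A [reference_set()].
#' @param mixtures A [beta_matrix()] of training mixtures.
#' @param truth The matching [mixture_truth()].
#' @return An `eval_report` (see [evaluate_estimates()]).
#' @export
score_library <- function(probes, ref, mixtures, truth) {
  lib <- assemble_library(ref, probes, method = "scored")
  fit <- deconvolve_matrix(mixtures, lib)
  evaluate_estimates(fit, truth)
}

#' Leave-one-out CpG impact on library accuracy
#'
#' For each CpG in the library, removes it, rescores the reduced library on
#' the training mixtures, and reports `delta = mean_rmse(without CpG) -
#' mean_rmse(full library)`. Positive delta means the CpG is beneficial
#' (dropping it hurts accuracy).
#'
#' @inheritParams score_library
#' @return Tibble with `probe_id` and `delta` (percentage points).
#' @export
assess_cpg_impacts <- function(probes, ref, mixtures, truth) {
  if (length(probes) < 2) stop("Need at least 2 probes", call. = FALSE)
  inp <- idol_inputs(probes, ref, mixtures, truth)
  X <- inp$means
  XtX <- crossprod(X)
  XtY <- crossprod(X, inp$Y)
  base <- score_cross(XtX, XtY, inp$truth)[["mean_rmse"]]
  delta <- vapply(seq_along(probes), function(i) {
    x <- X[i, ]
    loo <- score_cross(XtX - tcrossprod(x), XtY - tcrossprod(x, inp$Y[i, ]),
                       inp$truth)
    loo[["mean_rmse"]] - base
  }, numeric(1))
  tibble::tibble(probe_id = probes, delta = delta)
}

#' Update inclusion probabilities from leave-one-out impacts
#'
#' Multiplicative rule on the sampled CpGs only: beneficial CpGs
#' (`delta > 0`) get `weight * (1 + eta)`, the rest `weight * (1 - eta)`,
#' both clamped to `[p_min, 1]`. Unsampled CpGs keep their weights.
#'
#' @param weights Named inclusion-weight vector over the pool.
#' @param impacts Tibble from [assess_cpg_impacts()].
#' @param eta,p_min,impact_tol See [idol_config()].
#' @return Updated weight vector.
#' @export
update_inclusion_probabilities <- function(weights, impacts, eta = 0.05,
                                           p_min = 0.01, impact_tol = 0) {
  up <- impacts$probe_id[impacts$delta > impact_tol]
  down <- impacts$probe_id[impacts$delta <= impact_tol]
  weights[up] <- pmin(pmax(weights[up] * (1 + eta), p_min), 1)
  weights[down] <- pmin(pmax(weights[down] * (1 - eta), p_min), 1)
  weights
}

#' Run the IDOL optimizer at a fixed library size
#'
#' Starting from equal inclusion weights over the candidate pool, each
#' iteration (1) draws a size-S library by weighted sampling, (2) scores it
#' on the training mixtures by constrained projection, (3) computes each
#' sampled CpG's leave-one-out impact, and (4) updates the inclusion
#' weights. The library with the lowest mean RMSE seen so far is kept (ties
#' broken by higher mean R^2, then by the earlier iteration).
#'
#' @param pool A `candidate_pool` from [build_candidate_pool()], or a
#'   character vector of probe IDs.
#' @param ref A [reference_set()].
#' @param mixtures A [beta_matrix()] of training mixtures (complete over
#'   the pool).
#' @param truth The matching [mixture_truth()].
#' @param config An [idol_config()]; `config$library_size` is S.
#' @return An `idol_state`: list with `best_library` (probe IDs),
#'   `best_score` (`mean_rmse`, `mean_r2`), `best_iteration`, `weights`,
#'   `history` (tibble: `iteration`, `mean_rmse`, `mean_r2`, `best_rmse`,
#'   `accepted`), and `config`.
#' @export
run_idol <- function(pool, ref, mixtures, truth, config = idol_config()) {
  probes <- if (inherits(pool, "candidate_pool")) pool$probes else pool
  S <- config$library_size
  if (S > length(probes)) {
    stop(sprintf("Library size %d exceeds pool size %d", S, length(probes)),
         call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  inp <- idol_inputs(probes, ref, mixtures, truth)
  X_pool <- inp$means                       # pool probes x 12
  # equal weights at mid-range so early updates can move both directions
  weights <- stats::setNames(rep(0.5, length(probes)), probes)

  best <- list(library = NULL, score = c(mean_rmse = Inf, mean_r2 = -Inf),
               iteration = NA_integer_)
  hist <- vector("list", config$n_iterations)
  for (it in seq_len(config$n_iterations)) {
    sampled <- sample_candidate_library(weights, S)
    idx <- match(sampled, probes)
    X <- X_pool[idx, , drop = FALSE]
    Y <- inp$Y[idx, , drop = FALSE]
    XtX <- crossprod(X)
    XtY <- crossprod(X, Y)
    sc <- score_cross(XtX, XtY, inp$truth)
    accepted <- sc[["mean_rmse"]] < best$score[["mean_rmse"]] ||
      (sc[["mean_rmse"]] == best$score[["mean_rmse"]] &&
         sc[["mean_r2"]] > best$score[["mean_r2"]])
    if (accepted) {
      best <- list(library = sampled, score = sc, iteration = it)
    }
    delta <- vapply(seq_len(S), function(i) {
      x <- X[i, ]
      loo <- score_cross(XtX - tcrossprod(x), XtY - tcrossprod(x, Y[i, ]),
                         inp$truth)
      loo[["mean_rmse"]] - sc[["mean_rmse"]]
    }, numeric(1))
    weights <- update_inclusion_probabilities(
      weights, tibble::tibble(probe_id = sampled, delta = delta),
      eta = config$eta, p_min = config$p_min,
      impact_tol = config$impact_tol %||% 0)
    hist[[it]] <- tibble::tibble(
      iteration = it, mean_rmse = sc[["mean_rmse"]],
      mean_r2 = sc[["mean_r2"]], best_rmse = best$score[["mean_rmse"]],
      accepted = accepted)
  }
  structure(
    list(best_library = sort(best$library), best_score = best$score,
         best_iteration = best$iteration, weights = weights,
         history = dplyr::bind_rows(hist), config = config),
    class = "idol_state")
}

#' @export
print.idol_state <- function(x, ...) {
  cat(sprintf(
    "idol_state: S = %d, %d iterations; best mean RMSE %.4f pp (R2 %.4f) at iteration %d\n",
    x$config$library_size, nrow(x$history), x$best_score[["mean_rmse"]],
    x$best_score[["mean_r2"]], x$best_iteration))
  invisible(x)
}

#' @export
tidy.idol_state <- function(x, ...) x$history

#' @export
glance.idol_state <- function(x, ...) {
  tibble::tibble(
    library_size = x$config$library_size,
    n_iterations = nrow(x$history),
    best_mean_rmse = x$best_score[["mean_rmse"]],
    best_mean_r2 = x$best_score[["mean_r2"]],
    best_iteration = x$best_iteration)
}

#' Optimize over a grid of library sizes
#'
#' Runs [run_idol()] at every size in `config$size_grid` (sizes exceeding
#' the pool are skipped with a warning) and selects the size whose best
#' library has the lowest mean RMSE; exact ties go to the smaller library
#' (parsimony). Per-size seeds are derived deterministically from
#' `config$seed`.
#'
#' @inheritParams run_idol
#' @return An `idol_grid`: list with `summary` (tibble: `library_size`,
#'   `mean_rmse`, `mean_r2`, `best_iteration`, `optimal`), `states` (one
#'   `idol_state` per size), `optimal_size`, `optimal_library`.
#' @export
run_idol_grid <- function(pool, ref, mixtures, truth, config = idol_config()) {
  probes <- if (inherits(pool, "candidate_pool")) pool$probes else pool
  sizes <- config$size_grid
  usable <- sizes[sizes <= length(probes)]
  if (length(usable) < length(sizes)) {
    warning(sprintf("%d grid size(s) exceed the pool (%d probes) and were skipped",
                    length(sizes) - length(usable), length(probes)))
  }
  if (length(usable) == 0) stop("No usable grid size", call. = FALSE)
  states <- purrr::imap(stats::setNames(usable, usable), function(S, i) {
    cfg <- config
    cfg$library_size <- S
    if (!is.null(config$seed)) cfg$seed <- config$seed + match(S, usable)
    run_idol(pool, ref, mixtures, truth, cfg)
  })
  summary <- purrr::map_dfr(states, glance) %>%
    dplyr::rename(mean_rmse = "best_mean_rmse", mean_r2 = "best_mean_r2") %>%
    dplyr::select("library_size", "mean_rmse", "mean_r2", "best_iteration")
  opt_idx <- order(summary$mean_rmse, summary$library_size)[1]
  summary$optimal <- seq_len(nrow(summary)) == opt_idx
  structure(
    list(summary = summary, states = states,
         optimal_size = summary$library_size[opt_idx],
         optimal_library = states[[opt_idx]]$best_library),
    class = "idol_grid")
}

#' @export
print.idol_grid <- function(x, ...) {
  cat(sprintf("idol_grid: %d sizes; optimum S = %d (mean RMSE %.4f pp)\n",
              nrow(x$summary), x$optimal_size,
              x$summary$mean_rmse[x$summary$optimal]))
  invisible(x)
}

#' @export
tidy.idol_grid <- function(x, ...) x$summary

#' Export an IDOL run log / grid summary
#'
#' `write_idol_log()` writes one JSON record per iteration (iteration,
#' mean_rmse, mean_r2, accepted flag); `write_grid_summary()` writes the
#' per-size table as TSV with an `optimal` flag column.
#'
#' @param state An `idol_state` or `idol_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_idol_log <- function(state, path) {
  recs <- purrr::pmap_chr(state$history, function(iteration, mean_rmse,
                                                  mean_r2, best_rmse,
                                                  accepted) {
    jsonlite::toJSON(list(iteration = iteration, mean_rmse = mean_rmse,
                          mean_r2 = mean_r2, accepted = accepted),
                     auto_unbox = TRUE, digits = NA)
  })
  writeLines(recs, path)
  invisible(path)
}

#' @rdname write_idol_log
#' @export
write_grid_summary <- function(state, path) {
  readr::write_tsv(state$summary, path, progress = FALSE)
  invisible(path)
}
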