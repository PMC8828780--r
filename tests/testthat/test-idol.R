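# IDOL optimizer mechanics: weighted sampling, probability updates,
# leave-one-out impacts, best-so-far selection, and the size grid.
# (The full planted-pool recovery experiment lives in test-acceptance.R.)

small_idol_fixture <- function(seed = 81) {
  cfg <- sim_config(markers_per_type = 4, n_background_probes = 0,
                    n_noise_probes = 100, noise_sd = 0.01,
                    purity_range = c(1, 1), n_mixtures = 12, seed = seed)
  sim <- simulate_reference(cfg)
  mix <- simulate_mixtures(sim$methylomes, cfg)
  c(sim, mix, list(config = cfg, pool = rownames(sim$methylomes)))
}

test_that("weighted sampling is exact in size, deterministic, and weight-driven", {
  w <- setNames(rep(1, 20), sprintf("cg%02d", 1:20))
  expect_setequal(sample_candidate_library(w, 20), names(w))
  expect_error(sample_candidate_library(w, 21), "exceeds pool")

  set.seed(1); a <- sample_candidate_library(w, 5)
  set.seed(1); b <- sample_candidate_library(w, 5)
  expect_identical(a, b)

  # one heavy probe among 4 at the floor: selection probability for S = 1
  # is 1 / (1 + 4 * 0.01); check the empirical rate against a 4-sigma
  # binomial band around that value
  w2 <- setNames(c(1, rep(0.01, 4)), sprintf("cg%d", 1:5))
  p <- 1 / (1 + 4 * 0.01)
  set.seed(2)
  hits <- mean(replicate(10000, sample_candidate_library(w2, 1) == "cg1"))
  expect_lt(abs(hits - p), 4 * sqrt(p * (1 - p) / 10000))
})

test_that("probability updates follow the clamped multiplicative rule", {
  w <- c(a = 1, b = 0.01, c = 0.5, d = 0.5)
  imp <- tibble::tibble(probe_id = c("a", "b", "c", "d"),
                        delta = c(0.2, -0.3, 0.1, -0.1))
  w2 <- update_inclusion_probabilities(w, imp, eta = 0.05, p_min = 0.01)
  expect_equal(unname(w2["a"]), 1)          # beneficial at cap stays 1
  expect_equal(unname(w2["b"]), 0.01)       # detrimental at floor stays
  expect_equal(unname(w2["c"]), 0.525)      # 0.5 * 1.05
  expect_equal(unname(w2["d"]), 0.475)      # 0.5 * 0.95
  # probes not in the impact table are untouched
  w3 <- update_inclusion_probabilities(w, imp[1:2, ], eta = 0.05)
  expect_equal(w3[c("c", "d")], w[c("c", "d")])
  # the impact tolerance reclassifies small positives as non-beneficial
  w4 <- update_inclusion_probabilities(w, imp, eta = 0.05, impact_tol = 0.15)
  expect_equal(unname(w4["c"]), 0.475)
})

test_that("leave-one-out impacts behave for redundant, critical and noise probes", {
  fx <- small_idol_fixture()
  markers <- fx$marker_map$probe_id
  # one marker per type + one noise probe
  solo <- fx$marker_map %>%
    dplyr::group_by(cell_type) %>%
    dplyr::slice(1) %>%
    dplyr::pull(probe_id)
  noise1 <- grep("^cg_noise_", fx$pool, value = TRUE)[1]
  imp <- assess_cpg_impacts(c(solo, noise1), fx$reference, fx$mixtures,
                            fx$truth)
  # sole discriminating markers: removal collapses identifiability, so
  # every delta is positive; the effect in mean-RMSE percentage points
  # scales with the type's abundance, so the rare-type minimum is small
  # while common types show large losses
  expect_true(all(imp$delta[imp$probe_id %in% solo] > 0.01))
  expect_gt(max(imp$delta[imp$probe_id %in% solo]), 0.5)
  # pure noise probe: removal does not hurt (within solver tolerance)
  expect_lt(imp$delta[imp$probe_id == noise1], 0.05)

  # duplicated probe: identical beta row under two IDs -> both redundant
  dup_src <- solo[1]
  vals <- unclass(fx$reference$betas)
  vals_dup <- rbind(vals, dup = vals[dup_src, ])
  rownames(vals_dup) <- c(rownames(vals), "cg_dup")
  ref_dup <- reference_set(beta_matrix(vals_dup), fx$reference$labels)
  mvals <- unclass(fx$mixtures)
  mvals_dup <- rbind(mvals, dup = mvals[dup_src, ])
  rownames(mvals_dup) <- c(rownames(mvals), "cg_dup")
  imp_dup <- assess_cpg_impacts(c(solo, "cg_dup"), ref_dup,
                                beta_matrix(mvals_dup), fx$truth)
  both <- imp_dup$delta[imp_dup$probe_id %in% c(dup_src, "cg_dup")]
  expect_lt(max(abs(both)), 0.02)           # neither copy is critical

  expect_error(assess_cpg_impacts(solo[1], fx$reference, fx$mixtures,
                                  fx$truth), "at least 2")
})

test_that("score_library composes assembly, deconvolution and evaluation", {
  fx <- small_idol_fixture()
  rep <- score_library(fx$marker_map$probe_id, fx$reference, fx$mixtures,
                       fx$truth)
  expect_s3_class(rep, "eval_report")
  expect_lt(glance(rep)$mean_rmse, 1)
  # a random same-size library from the diluted pool scores worse
  set.seed(3)
  rand <- sample(fx$pool, nrow(fx$marker_map))
  rep_rand <- score_library(rand, fx$reference, fx$mixtures, fx$truth)
  expect_gt(glance(rep_rand)$mean_rmse, glance(rep)$mean_rmse)
})

test_that("run_idol keeps the best library, monotone best-RMSE, reproducibly", {
  fx <- small_idol_fixture()
  cfg1 <- idol_config(library_size = 48, n_iterations = 1, seed = 5)
  one <- run_idol(fx$pool, fx$reference, fx$mixtures, fx$truth, cfg1)
  expect_equal(one$best_iteration, 1)       # single iteration is the best
  expect_equal(nrow(one$history), 1)

  cfg <- idol_config(library_size = 48, n_iterations = 8, seed = 5,
                     eta = 0.3, impact_tol = 2e-4)
  a <- run_idol(fx$pool, fx$reference, fx$mixtures, fx$truth, cfg)
  expect_false(is.unsorted(-a$history$best_rmse))   # non-increasing
  expect_equal(a$history$mean_rmse[a$best_iteration],
               a$best_score[["mean_rmse"]])
  b <- run_idol(fx$pool, fx$reference, fx$mixtures, fx$truth, cfg)
  expect_identical(a$history, b$history)            # bit-identical rerun
  expect_identical(a$best_library, b$best_library)
  expect_true(all(a$weights >= cfg$p_min & a$weights <= 1))
})

test_that("with the pool equal to the perfect markers run_idol is near-exact", {
  cfg0 <- sim_config(markers_per_type = 4, n_background_probes = 0,
                     noise_sd = 0, purity_range = c(1, 1),
                     n_mixtures = 8, seed = 82)
  sim <- simulate_reference(cfg0)
  mix <- simulate_mixtures(sim$methylomes, cfg0)
  pool <- sim$marker_map$probe_id
  st <- run_idol(pool, sim$reference, mix$mixtures, mix$truth,
                 idol_config(library_size = length(pool), n_iterations = 1,
                             seed = 6))
  expect_setequal(st$best_library, pool)
  expect_lt(st$best_score[["mean_rmse"]], 1e-6)
})

test_that("the size grid skips oversized entries and selects the best size", {
  fx <- small_idol_fixture()
  cfg <- idol_config(n_iterations = 4, seed = 7, eta = 0.3,
                     size_grid = c(12, 96, 10000))
  expect_warning(grid <- run_idol_grid(fx$pool, fx$reference, fx$mixtures,
                                       fx$truth, cfg), "skipped")
  expect_equal(grid$summary$library_size, c(12, 96))
  # with 96 planted markers available, the larger library dominates
  expect_lte(grid$summary$mean_rmse[2], grid$summary$mean_rmse[1])
  expect_equal(grid$optimal_size, 96)
  expect_equal(sum(grid$summary$optimal), 1)

  single <- run_idol_grid(fx$pool, fx$reference, fx$mixtures, fx$truth,
                          idol_config(n_iterations = 2, seed = 8,
                                      size_grid = 24))
  expect_equal(single$optimal_size, 24)
})

test_that("run logs serialize as JSON lines and grid summaries as TSV", {
  fx <- small_idol_fixture()
  st <- run_idol(fx$pool, fx$reference, fx$mixtures, fx$truth,
                 idol_config(library_size = 48, n_iterations = 3, seed = 9))
  log_path <- tempfile(fileext = ".jsonl")
  write_idol_log(st, log_path)
  recs <- lapply(readLines(log_path), jsonlite::fromJSON)
  expect_length(recs, 3)
  expect_equal(recs[[2]]$iteration, 2)
  expect_equal(recs[[2]]$mean_rmse, st$history$mean_rmse[2])

  grid <- run_idol_grid(fx$pool, fx$reference, fx$mixtures, fx$truth,
                        idol_config(n_iterations = 2, seed = 10,
                                    size_grid = c(24, 48)))
  tsv_path <- tempfile(fileext = ".tsv")
  write_grid_summary(grid, tsv_path)
  back <- readr::read_tsv(tsv_path, show_col_types = FALSE)
  expect_equal(back$library_size, c(24, 48))
  expect_equal(sum(back$optimal), 1)
})
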