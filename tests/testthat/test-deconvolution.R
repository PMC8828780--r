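# Constrained projection: exact recovery cases, agreement with a
# brute-force simplex oracle, per-sample missingness handling, and the
# methylation-purity screen.

test_that("a pure cell type and an even two-type blend are recovered exactly", {
  panel <- pure_panel(seed = 51, markers = 6, bg = 20)
  lib <- auto_select_library(panel$reference, n_per_direction = 6)
  X <- lib$means
  fit <- cpqp_deconvolve(X[, "Treg"], lib)
  e_k <- setNames(as.numeric(cell_types() == "Treg"), cell_types())
  expect_equal(fit$raw, e_k, tolerance = 1e-6)
  expect_lt(fit$residual, 1e-6)

  blend <- 0.5 * X[, "Bnv"] + 0.5 * X[, "CD8mem"]
  fit <- cpqp_deconvolve(blend, lib)
  expect_equal(unname(fit$raw[c("Bnv", "CD8mem")]), c(0.5, 0.5),
               tolerance = 1e-6)
  expect_equal(sum(fit$raw), 1, tolerance = 1e-6)
})

test_that("QP solution matches the simplex grid-search oracle on small instances", {
  set.seed(52)
  types3 <- c("Neu", "CD4nv", "NK")
  for (i in 1:20) {
    K <- sample(2:3, 1)
    n_p <- sample(3:6, 1)
    X <- matrix(runif(n_p * K), n_p, K,
                dimnames = list(sprintf("cg%d", seq_len(n_p)), types3[1:K]))
    w_true <- rgamma(K, 1); w_true <- w_true / sum(w_true) * runif(1, 0.6, 1)
    y <- as.numeric(X %*% w_true) + rnorm(n_p, sd = 0.02)
    y <- pmin(pmax(y, 0), 1)
    names(y) <- rownames(X)
    lib <- leukodeconv:::new_deconv_library(X)
    w_qp <- cpqp_deconvolve(y, lib)$raw
    w_grid <- grid_oracle(y, X)
    expect_lt(max(abs(w_qp - w_grid)), 2e-4)
  }
})

test_that("solutions satisfy the constraints and ignore probe order", {
  set.seed(53)
  panel <- pure_panel(seed = 53, markers = 5, bg = 10)
  lib <- auto_select_library(panel$reference, n_per_direction = 5)
  y <- runif(nrow(lib$means))
  names(y) <- lib$probe_ids
  fit <- cpqp_deconvolve(y, lib)
  expect_true(all(fit$raw >= 0))
  expect_lte(sum(fit$raw), 1 + 1e-6)
  # permute library probes: estimates unchanged
  perm <- sample(length(lib$probe_ids))
  lib_perm <- leukodeconv:::new_deconv_library(
    lib$means[perm, ], method = "manual")
  fit_perm <- cpqp_deconvolve(y[perm], lib_perm)
  expect_equal(fit_perm$raw, fit$raw, tolerance = 1e-8)
})

test_that("rank-deficient designs warn but still return a solution", {
  X <- matrix(c(0.1, 0.9, 0.5, 0.1, 0.9, 0.5), 3, 2,
              dimnames = list(c("cg1", "cg2", "cg3"), c("Neu", "NK")))
  lib <- leukodeconv:::new_deconv_library(X)
  y <- setNames(c(0.1, 0.9, 0.5), rownames(X))
  expect_warning(fit <- cpqp_deconvolve(y, lib), "rank-deficient")
  expect_true(all(is.finite(fit$raw)))
  expect_error(cpqp_deconvolve(setNames(rep(NA_real_, 3), rownames(X)), lib),
               "missing")
})

test_that("matrix deconvolution drops missing probes per sample and gates on call rate", {
  panel <- pure_panel(seed = 54, markers = 6, bg = 0)
  lib <- auto_select_library(panel$reference, n_per_direction = 6)
  cfg <- panel$config
  mix <- simulate_mixtures(panel$methylomes, cfg)
  full <- deconvolve_matrix(mix$mixtures, lib)
  expect_true(all(full$samples$status == "ok"))
  # complete data: matrix path equals the per-sample path
  y1 <- unclass(mix$mixtures)[, 1]
  expect_equal(full$raw[1, ], cpqp_deconvolve(y1[lib$probe_ids], lib)$raw,
               tolerance = 1e-10)

  vals <- unclass(mix$mixtures)
  vals[sample(lib$probe_ids, round(0.1 * length(lib$probe_ids))), 2] <- NA
  vals[sample(lib$probe_ids, round(0.3 * length(lib$probe_ids))), 3] <- NA
  masked <- beta_matrix(vals)
  expect_warning(fit <- deconvolve_matrix(masked, lib), "call-rate")
  expect_equal(fit$samples$status[2], "warning")   # 90% call rate
  expect_equal(fit$samples$status[3], "error")     # 70% call rate
  expect_true(all(is.na(fit$raw[3, ])))
  expect_false(anyNA(fit$raw[-3, ]))               # others unaffected
  expect_equal(fit$samples$call_rate[2], 0.9, tolerance = 0.01)
})

test_that("methylation purity recovers known contamination", {
  panel <- pure_panel(seed = 55, markers = 8, bg = 20)
  lib <- auto_select_library(panel$reference, n_per_direction = 8)
  M <- panel$methylomes
  # pure sample equals its library column
  expect_equal(methylation_purity(lib$means[, "Eos"], lib, "Eos"), 1,
               tolerance = 1e-6)
  # 10% contamination by each possible contaminant
  for (other in c("Bas", "CD8nv", "Bmem")) {
    y <- 0.9 * M[, "Eos"] + 0.1 * M[, other]
    expect_equal(methylation_purity(y[lib$probe_ids], lib, "Eos"), 0.9,
                 tolerance = 0.02)
  }
  expect_error(methylation_purity(lib$means[, "Eos"],
                                  leukodeconv:::new_deconv_library(
                                    lib$means[, 1:4]), "NK"),
               "not a column")
})

test_that("the purity screen applies the strict >85% rule", {
  panel <- pure_panel(seed = 56, markers = 8, bg = 0)
  lib <- auto_select_library(panel$reference, n_per_direction = 8)
  M <- panel$methylomes
  # boundary samples constructed at exactly 0.85 and at 0.86
  mk <- function(p, ct, other) M[lib$probe_ids, ct] * p +
    M[lib$probe_ids, other] * (1 - p)
  vals <- cbind(at85 = mk(0.85, "Mono", "NK"), at86 = mk(0.86, "Mono", "NK"))
  ref <- reference_set(beta_matrix(vals),
                       c(at85 = "Mono", at86 = "Mono"))
  screen <- screen_reference_purity(ref, lib)
  expect_equal(screen$purity, c(0.85, 0.86), tolerance = 5e-3)
  expect_false(screen$pass[screen$sample_id == "at85"])
  expect_true(screen$pass[screen$sample_id == "at86"])
  expect_equal(screen$top_contaminant, c("NK", "NK"))

  # an all-pure panel passes everywhere
  all_pure <- screen_reference_purity(panel$reference, lib)
  expect_true(all(all_pure$pass))
})
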