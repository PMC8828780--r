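# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except through the round-trip tests' own temporary files.

# Tiny beta matrix with explicit values.
toy_beta <- function(values = matrix(c(0.1, 0.9, 0.5, 0.2, 0.8, 0.4), 3, 2),
                     probes = sprintf("cg%06d", seq_len(nrow(values))),
                     samples = sprintf("s%d", seq_len(ncol(values)))) {
  beta_matrix(values, probe_ids = probes, sample_ids = samples)
}

# Two-cell-type reference with perfectly separating probes plus optional
# shared probes; returns the reference and the per-type true profiles.
toy_two_type_ref <- function(n_per_type = 3, jitter = 0.01, seed = 1) {
  set.seed(seed)
  probes <- c("cg_neu_low", "cg_neu_high", "cg_nk_low", "cg_nk_high",
              "cg_shared")
  prof <- cbind(
    Neu = c(0.05, 0.95, 0.90, 0.10, 0.50),
    NK  = c(0.90, 0.10, 0.05, 0.95, 0.50))
  rownames(prof) <- probes
  vals <- cbind(
    prof[, rep("Neu", n_per_type)] + matrix(stats::rnorm(5 * n_per_type,
                                                         sd = jitter), 5),
    prof[, rep("NK", n_per_type)] + matrix(stats::rnorm(5 * n_per_type,
                                                        sd = jitter), 5))
  vals <- pmin(pmax(vals, 0), 1)
  samples <- c(sprintf("Neu_%d", seq_len(n_per_type)),
               sprintf("NK_%d", seq_len(n_per_type)))
  colnames(vals) <- samples
  labels <- stats::setNames(rep(c("Neu", "NK"), each = n_per_type), samples)
  list(ref = reference_set(beta_matrix(vals), labels), profiles = prof)
}

# Random non-degenerate truth matrix (uses the caller's RNG state).
rdirich_fixture <- function(n) {
  g <- matrix(stats::rgamma(n * 12, shape = 1), n)
  p <- g / rowSums(g)
  dimnames(p) <- list(sprintf("m%d", seq_len(n)), cell_types())
  mixture_truth(p)
}

# Uniform 12-type truth matrix.
uniform_truth <- function(n = 3) {
  mixture_truth(matrix(1 / 12, n, 12,
                       dimnames = list(sprintf("m%d", seq_len(n)),
                                       cell_types())))
}

# Brute-force simplex grid-search oracle for the constrained projection:
# minimizes ||y - X w||^2 over w >= 0, sum(w) <= 1 by successively refined
# grid passes down to resolution 1e-4 (the objective is convex, so refining
# around each pass's optimum is safe). Independent of the QP solver.
grid_oracle <- function(y, X, steps = c(0.02, 1e-3, 1e-4, 2e-5)) {
  K <- ncol(X)
  expand_w <- function(ranges, step) {
    pts <- lapply(ranges, function(r)
      seq(max(r[1], 0), min(r[2], 1), by = step))
    g <- as.matrix(expand.grid(pts))
    g[rowSums(g) <= 1 + 1e-12, , drop = FALSE]
  }
  ranges <- replicate(K, c(0, 1), simplify = FALSE)
  w0 <- NULL
  for (step in steps) {
    # at each scale, re-center the window until the argmin is interior
    # (flat valleys from near-collinear columns can otherwise escape it)
    for (pass in 1:60) {
      W <- expand_w(ranges, step)
      w0 <- W[which.min(colSums((y - X %*% t(W))^2)), ]
      lo <- vapply(ranges, `[`, numeric(1), 1)
      hi <- vapply(ranges, `[`, numeric(1), 2)
      on_edge <- (abs(w0 - pmax(lo, 0)) < step / 2 & lo > 0) |
        (abs(w0 - pmin(hi, 1)) < step / 2 & hi < 1)
      ranges <- lapply(seq_len(K), function(k)
        c(w0[k] - 3 * step, w0[k] + 3 * step))
      if (!any(on_edge)) break
    }
  }
  w0
}

# Small pure (noise-free, fully pure) simulated panel shared by tests.
pure_panel <- function(seed = 21, markers = 8, bg = 60) {
  cfg <- sim_config(markers_per_type = markers, n_background_probes = bg,
                    noise_sd = 0, purity_range = c(1, 1), seed = seed)
  sim <- simulate_reference(cfg)
  c(sim, list(config = cfg))
}
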