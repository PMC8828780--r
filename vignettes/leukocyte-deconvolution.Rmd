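---
title: "Reference-based leukocyte deconvolution of blood DNA methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-based leukocyte deconvolution of blood DNA methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leukodeconv)
```

## The model

Whole blood is a mixture of leukocyte subtypes, and each subtype carries a
distinctive DNA-methylation signature. If $y \in [0,1]^p$ is the vector of
beta values measured on a blood sample at $p$ selected CpGs, and
$X \in [0,1]^{p \times K}$ holds the mean methylation of the same CpGs in
purified reference samples of $K = 12$ leukocyte types, the observed
methylome is modelled as the proportion-weighted combination of the
reference methylomes:

$$\hat w \;=\; \arg\min_{w}\; \lVert y - X w \rVert^2
\quad\text{s.t.}\quad w \ge 0,\;\; \textstyle\sum_k w_k \le 1 .$$

This non-negative, sum-constrained least-squares problem — constrained
projection / quadratic programming (CP/QP) — is a convex quadratic program;
`cpqp_deconvolve()` solves it with `quadprog::solve.QP()`. Both the raw
solution (whose total may fall below one when the sample contains signal
from cell types absent from the library) and the normalized proportions
$\hat w / \sum_k \hat w_k$ are returned; downstream profiling uses the
normalized values so that derived counts decompose exactly.

The twelve base types are neutrophils (Neu), eosinophils (Eos), basophils
(Bas), monocytes (Mono), naive and memory B cells (Bnv, Bmem), naive and
memory CD4+ T cells (CD4nv, CD4mem), regulatory T cells (Treg), naive and
memory CD8+ T cells (CD8nv, CD8mem), and natural killer cells (NK).

## Probe quality filtering

Reference and target matrices are reduced to a high-quality analysis set
before any modelling:

1. `apply_quality_mask()` sets entries missing when the out-of-band
   detection p-value exceeds 0.05 (signal indistinguishable from
   background) or fewer than 3 beads support the probe.
2. `select_complete_probes()` keeps only probes observed in every sample.
   No imputation is performed — a masked signal may be cell-type dependent,
   so filling it in would bias reference means.
3. `filter_probes()` removes CpH (non-CpG) probes, chrX/chrY probes (their
   signal depends on sex-chromosome dosage), and probes on a user-supplied
   mask of polymorphic or cross-reactive assays.

Multiply-excludable probes are attributed to the first applicable step in
the report; the retained set is order-independent (property-tested).

## Building a library

`one_vs_rest_tstats()` scores every probe per cell type with a Welch
(unequal-variance) two-sample t-statistic, target-type samples versus all
other reference samples pooled. Welch is used because group sizes are small
(3–6 sorted samples) against a large heteroscedastic "rest" pool. Ties are
broken by lexicographic probe ID so libraries are reproducible and
independent of sample order.

Two selection strategies are provided:

* **Automatic** (`auto_select_library()`): per type, the top
  `n_per_direction` most hyper- and hypomethylated probes (default 50),
  deduplicated — 1200 probes for 12 types with no cross-type collisions.
* **IDOL** (`run_idol()` / `run_idol_grid()`): starting from a candidate
  pool (`build_candidate_pool()`, default L = 150 markers per type, split
  across directions), the optimizer repeatedly (1) draws a size-S library
  by weighted sampling without replacement, (2) deconvolves training
  mixtures of known composition and scores mean RMSE and mean $R^2$,
  (3) removes each sampled CpG in turn and records the change in mean RMSE
  (its leave-one-out impact), and (4) multiplies the inclusion weight of
  beneficial CpGs by $1+\eta$ and of the rest by $1-\eta$, clamped to
  $[p_{\min}, 1]$. The best library seen (lowest mean RMSE; ties to higher
  $R^2$, then the earlier iteration) is kept, and the grid search selects
  the size with the lowest best RMSE, preferring the smaller library on
  exact ties.

### Choosing the update rate

The defaults $\eta = 0.05$, $p_{\min} = 0.01$ suit runs of several hundred
iterations (the conventional 500): each pool CpG is then resampled often
enough for its weight to traverse the whole $[p_{\min}, 1]$ range. In a
short exploratory run the weights cannot concentrate at that rate — over 50
iterations a CpG is resampled only ~12 times, bounding its weight change
at $(1 \pm 0.05)^{12} \approx 1.8\times$ — so $\eta$ should be scaled up
roughly in inverse proportion to the iteration budget; the desk-scale
experiments in the test suite use $\eta = 0.6$ at 50 iterations. A small
`impact_tol` (the tests use $2\times10^{-4}$ percentage points) keeps the
sign noise of near-zero leave-one-out impacts (quadratic-programming
round-off averaged over few mixtures) from randomizing the up/down
classification of genuinely redundant probes.

## Reference purity screening

`methylation_purity()` projects a purified sample back onto the library and
reads off the normalized proportion of its own labeled type ("DNA
methylation purity"). `screen_reference_purity()` applies the inclusion
rule used when assembling reference panels: a sample is kept only when its
purity is *strictly greater* than 85%, and the report names the strongest
contaminant type per sample.

## The immune-profile layer

From the 12 normalized base proportions, `build_full_profile()` derives:

* 7 hierarchical aggregates — Bcell, CD4T, CD8T, Tcell, Gran, Lymphoid,
  Myeloid — giving 19 proportions whose sums satisfy the lineage algebra
  (Lymphoid + Myeloid = 1) to $10^{-6}$;
* 19 absolute counts (cells/µL) when a total leukocyte count is supplied,
  by multiplying each proportion by the count so component counts sum
  exactly to aggregate counts;
* 18 named ratios (`profile_ratio_definitions()`): the
  neutrophil-to-lymphocyte ratio, CD4:CD8, per-lineage and overall
  naive:memory ratios, lymphoid:myeloid, within-branch shares (Treg of
  CD4T, Eos and Bas of Gran), major-compartment shares of total, and
  Tcell:Bcell. The set is frozen and named so profiles are comparable
  across analyses; ratios with zero denominators are reported `NA`, never
  infinity.

That is 56 variables per sample with counts, 37 without.

## The simulator

`simulate_reference()` and `simulate_mixtures()` generate the ground-truth
world used by every test:

* per type, `markers_per_type` hypomethylated markers (own-type beta in
  [0, 0.15], other types in [0.7, 1]) and as many hypermethylated markers
  (ranges reversed), on a background of probes whose beta is shared by all
  types (drawn from a bimodal Beta(0.4, 0.4), like the U-shaped beta
  distribution of real arrays);
* optional *pure-noise probes* whose expected beta is also shared but
  whose every measurement carries independent Gaussian noise (sd 0.2 by
  default), emulating CpGs with high cell-type-independent variability —
  these actively distort deconvolution fits and are the dilution used in
  marker-importance experiments (quiet background probes are not suitable
  for that role: being constant, they mildly *help* the fit through the
  sum constraint rather than hurting it);
* reference samples with per-sample purity drawn uniformly from
  `purity_range` (default 0.85–0.99, the range reported for
  immunomagnetically sorted leukocytes), contaminated by a single random
  other type — the hardest pattern for the purity screen — plus truncated
  Gaussian beta noise (sd 0.01 by default);
* mixtures $y = Mw + \varepsilon$ with $w$ drawn from a twelve-component
  Dirichlet. Per-type sample counts default to (6, 4, 6, 5, 4, 6, 5, 4, 3,
  5, 4, 4) for Neu…NK, a realistic 56-sample sorted panel.

Two Dirichlet parameterizations serve different roles. The default alpha
is skewed toward neutrophils and CD4 T cells so draws resemble adult blood
(useful when exercising the profile layer). Validation-mixture experiments
instead use a uniform Dirichlet (`dirichlet_alpha = rep(1, 12)`): every
type then spans a usable dynamic range across mixtures, which is how
reconstruction experiments are designed — with blood-like skew a ~1%
compartment has almost no between-mixture variance and its $R^2$ against
truth is noise-limited regardless of estimator quality.

Similarly, the *parameter-recovery* experiments build libraries from fully
pure references (`purity_range = c(1, 1)`): they measure estimator
correctness under measurement noise. Contamination robustness is measured
separately by the purity screen, because contaminated reference means bias
any deconvolution method and would confound the recovery readout.

What the simulator does **not** model: probe-level intensity channels,
batch/slide effects, correlated noise between probes, cell types outside
the 12 (e.g. nucleated red blood cells), and biologically shared markers
between hierarchically close subtypes (planted markers are perfectly
type-specific). Passing tests therefore demonstrate correctness of the
estimators and selection machinery, not field performance on real arrays.

## Numerical choices

* The QP is solved from crossproducts; if $X^\top X$ is numerically
  rank-deficient (duplicate cell-type columns), a tiny ridge
  ($10^{-8} \max \mathrm{diag}$) restores positive definiteness and a
  degeneracy warning is raised. Solver round-off below zero is clipped;
  sums marginally above one are rescaled.
* Samples are deconvolved on the library probes they actually carry
  (per-sample dropping, so mixed 450k/EPIC inputs lose no samples); the
  call rate used is recorded, samples under 80% are refused, and samples
  under 95% flagged.
* $R^2$ is the squared Pearson correlation per cell type, the convention
  of scatterplot validation against flow cytometry; it is undefined (and
  excluded from means) when the truth column is constant. RMSE is reported
  in percentage points.
* Evaluation, profile and count layers run on normalized proportions.
* IDOL per-size seeds in the grid are derived as `seed + size index` so
  the whole grid is reproducible from one integer.

## Desk-scale experiment sizes

The test suite and the acceptance script run the whole pipeline at sizes
chosen to finish in minutes on one core while leaving the conclusions
unambiguous: panels of 56 reference samples, 20 planted markers per type
per direction, 24 mixtures for recovery experiments; a 960-probe pool
(240 markers + 720 noise probes), S = 240 and 50 iterations for the IDOL
recovery experiment; 100 fuzzed instances against a brute-force simplex
grid-search oracle (resolution $2\times10^{-5}$ after successive
refinement) for the QP.

## Known limitations

* The multiplicative probability update is one member of the family of
  plausible IDOL update rules; magnitude-weighted updates could converge
  faster but are harder to bound.
* With marker-redundant libraries, leave-one-out impacts of individual
  markers shrink toward zero, so weight concentration saturates before
  100% of planted markers are recovered.
* The purity screen shares information with the library when the library
  was built from the same samples; screening against an independently
  assembled library is preferable when available.
* Real reference panels carry slide/chip variance that the simulator does
  not emulate; context enrichment of real libraries (open-sea enrichment
  of selected markers) can only be reproduced with real annotation.
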