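Package: leukodeconv
Title: Reference-Based Leukocyte Deconvolution of Blood DNA Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the cellular composition of peripheral
    blood from DNA methylation microarray beta values. Builds deconvolution
    reference libraries for 12 leukocyte subtypes (neutrophils, eosinophils,
    basophils, monocytes, naive and memory B cells, naive and memory CD4+ and
    CD8+ T cells, regulatory T cells, and natural killer cells) by automatic
    marker selection or by iterative library optimization (IDOL), estimates
    mixture proportions by constrained projection / quadratic programming,
    screens sorted reference samples for methylation purity, derives a
    56-variable immune profile (hierarchical aggregates, absolute counts,
    and named cell ratios), and simulates synthetic reference panels and
    Dirichlet artificial mixtures with ground truth for validation.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    quadprog,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
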