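Package: ifnscore
Title: Two-Score Interferon-Stimulated Gene Signatures from qPCR Delta-Ct Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Derives continuous interferon-stimulated-gene (ISG) expression
    scores (IFN Score A and IFN Score B) from TaqMan qPCR delta-Ct data.
    Implements the full derivation pipeline: delta-Ct normalization to a
    reference gene, single imputation of censored nondetects under a
    censored-normal EM model, sampling-adequacy diagnostics (KMO, Bartlett's
    sphericity, determinant and squared-multiple-correlation screens), Horn's
    parallel analysis, iterated principal-axis factoring with oblique promax
    rotation, loading-threshold gene assignment, and median delta-Ct factor
    scores. Samples are classified as IFN-high or IFN-low by univariate
    Gaussian finite mixture models selected by AIC/BIC, and clinical
    validation statistics are provided: age-adjusted expression ratios with
    Tukey-adjusted contrasts and partial omega/eta squared effect sizes,
    covariate association models, Mann-Whitney contrasts, predictive-mean-
    matching multiple imputation and Rubin's-rules pooling. A configurable
    synthetic-cohort generator emulates the oblique two-factor structure,
    group shifts, bimodal mixtures and Ct-censoring of autoimmune-disease
    qPCR panels so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
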