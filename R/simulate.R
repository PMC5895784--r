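#' Synthetic-cohort configuration
#'
#' Builds the configuration for [generate_cohort()]. Defaults are read from
#' the packaged `cohort-defaults.yaml`, which encodes the validation-cohort
#' group sizes and age distributions, the packaged panel loadings with the
#' published inter-factor correlation, and latent group shifts chosen to
#' reproduce the published contrast geometry (Score A elevated in SLE only;
#' Score B elevated in SLE and RA). Any element can be overridden.
#'
#' @param ... Named overrides of the default configuration: `group_sizes`
#'   (named integers), `pattern_loadings` (genes x 2 matrix),
#'   `factor_correlation`, `group_factor_shifts` (named list of length-2
#'   vectors, positive = higher expression), `uniqueness` (per-gene residual
#'   variances; default `1 - communality` from the loadings),
#'   `gene_baseline`, `ct_ceiling`, `ref_ct_mean`, `ref_ct_sd`, `age`
#'   (named list of `c(mean, sd)`), `mixture` (optional
#'   `list(proportion_high, separation)` adding a within-group bimodal shift
#'   of latent factor A), `seed`.
#' @param panel Panel supplying gene names and loadings (default
#'   [ifn_panel()]).
#' @return A list of class `ifn_cohort_config`.
#' @export
cohort_config <- function(..., panel = ifn_panel()) {
  defaults <- yaml::read_yaml(system.file("extdata", "cohort-defaults.yaml",
                                          package = "ifnscore"))
  L <- cbind(panel$loading_a, panel$loading_b)
  rownames(L) <- panel$gene
  cfg <- list(
    group_sizes = unlist(defaults$group_sizes),
    pattern_loadings = L,
    factor_correlation = defaults$factor_correlation,
    group_factor_shifts = lapply(defaults$group_factor_shifts, as.numeric),
    uniqueness = NULL,
    gene_baseline = defaults$gene_baseline,
    ct_ceiling = defaults$ct_ceiling,
    ref_ct_mean = defaults$ref_ct_mean,
    ref_ct_sd = defaults$ref_ct_sd,
    age = lapply(defaults$age, as.numeric),
    mixture = NULL,
    ana_count_base = defaults$ana_count_base,
    ana_count_slope = defaults$ana_count_slope,
    lymphocyte_log_mean = defaults$lymphocyte_log_mean,
    lymphocyte_log_sd = defaults$lymphocyte_log_sd,
    lymphocyte_slope = defaults$lymphocyte_slope,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    stop("Unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  if (is.null(cfg$uniqueness)) {
    Phi <- matrix(c(1, cfg$factor_correlation, cfg$factor_correlation, 1), 2)
    h2 <- rowSums((cfg$pattern_loadings %*% Phi) * cfg$pattern_loadings)
    cfg$uniqueness <- pmax(1 - h2, 0.02)
  }
  stopifnot(all(cfg$group_sizes > 0), all(cfg$uniqueness >= 0),
            abs(cfg$factor_correlation) < 1)
  if (!setequal(names(cfg$group_sizes), names(cfg$group_factor_shifts))) {
    stop("group_sizes and group_factor_shifts must name the same groups",
         call. = FALSE)
  }
  class(cfg) <- "ifn_cohort_config"
  cfg
}

#' Generate a synthetic qPCR cohort
#'
#' Draws per-sample latent factors from a bivariate normal with the
#' configured correlation, shifted by diagnostic group (and by a bimodal
#' high/low component when `mixture` is configured); gene delta-Ct is
#' `baseline - pattern %*% factor + N(0, uniqueness)`, so positive latent
#' shifts mean higher expression. Ct is reconstructed as
#' `dct + reference Ct`, values above `ct_ceiling` are marked nondetect,
#' and ages plus simple parametric clinical covariates (ANA count via a
#' capped Poisson link to latent factor A, log-normal lymphocyte count with
#' a negative link, logistic BILAG-domain indicators) are attached. The
#' truth record stores every latent value and parameter for recovery tests.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg An `ifn_cohort_config` from [cohort_config()].
#' @return List with `ct` (long Ct tibble including the PPIA reference
#'   rows), `meta` (sample metadata), and `truth` (latent factors and
#'   parameters).
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "ifn_cohort_config"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(cfg$seed)

  L <- cfg$pattern_loadings
  p <- nrow(L)
  genes <- rownames(L)
  rho <- cfg$factor_correlation
  Phi <- matrix(c(1, rho, rho, 1), 2)
  ch <- chol(Phi)

  groups <- names(cfg$group_sizes)
  n_total <- sum(cfg$group_sizes)
  diagnosis <- rep(groups, times = cfg$group_sizes)
  sample_id <- sprintf("S%03d", seq_len(n_total))

  fmat <- matrix(stats::rnorm(n_total * 2), n_total, 2) %*% ch
  comp_high <- rep(FALSE, n_total)
  for (g in groups) {
    idx <- which(diagnosis == g)
    shift <- cfg$group_factor_shifts[[g]]
    fmat[idx, 1] <- fmat[idx, 1] + shift[1]
    fmat[idx, 2] <- fmat[idx, 2] + shift[2]
  }
  if (!is.null(cfg$mixture)) {
    comp_high <- stats::runif(n_total) < cfg$mixture$proportion_high
    fmat[comp_high, 1] <- fmat[comp_high, 1] + cfg$mixture$separation
  }

  E <- matrix(stats::rnorm(n_total * p), n_total, p) %*%
    diag(sqrt(cfg$uniqueness), p)
  dct <- matrix(cfg$gene_baseline, n_total, p) - fmat %*% t(L) + E
  colnames(dct) <- genes

  ref_ct <- stats::rnorm(n_total, cfg$ref_ct_mean, cfg$ref_ct_sd)
  ct_mat <- dct + ref_ct
  nondetect <- ct_mat > cfg$ct_ceiling

  ct <- tibble::tibble(
    sample_id = rep(sample_id, times = p),
    gene = rep(genes, each = n_total),
    ct = ifelse(as.vector(nondetect), NA_real_, as.vector(ct_mat)),
    detected = !as.vector(nondetect)
  )
  ref_rows <- tibble::tibble(sample_id = sample_id, gene = "PPIA",
                             ct = ref_ct, detected = TRUE)
  ct <- dplyr::bind_rows(ct, ref_rows)

  # standardized latent factors within the cohort drive the covariates
  fa_std <- as.numeric(scale(fmat[, 1]))
  fb_std <- as.numeric(scale(fmat[, 2]))
  is_patient <- diagnosis != "HC"
  age <- vapply(seq_len(n_total), function(i) {
    pars <- cfg$age[[diagnosis[i]]]
    stats::rnorm(1, pars[1], pars[2])
  }, numeric(1))
  age <- pmax(age, 18)
  ana <- pmin(stats::rpois(n_total, exp(cfg$ana_count_base +
                                          cfg$ana_count_slope * fa_std)), 8L)
  ana[diagnosis == "HC"] <- pmin(stats::rpois(sum(!is_patient), 0.05), 8L)
  lymph <- exp(stats::rnorm(n_total, cfg$lymphocyte_log_mean +
                              cfg$lymphocyte_slope * fa_std,
                            cfg$lymphocyte_log_sd))
  logit <- function(x) 1 / (1 + exp(-x))
  meta <- tibble::tibble(
    sample_id = sample_id,
    diagnosis = diagnosis,
    age = age,
    ana_count = as.integer(ana),
    lymphocyte_count = lymph,
    low_complement = stats::runif(n_total) < logit(-2 + 0.8 * fa_std) & is_patient,
    dsdna_titre = exp(stats::rnorm(n_total, 1.5 + 0.5 * fa_std, 1)) *
      as.numeric(is_patient),
    bilag_mucocutaneous = stats::runif(n_total) < logit(-1.5 + 0.7 * fa_std) & is_patient,
    bilag_musculoskeletal = stats::runif(n_total) < logit(-1.2) & is_patient,
    bilag_haematological = stats::runif(n_total) < logit(-1.5 + 0.6 * fb_std) & is_patient,
    flare = stats::runif(n_total) < logit(-1.8 + 0.6 * fa_std) & is_patient,
    internal_organ = stats::runif(n_total) < logit(-1.5 + 0.5 * fb_std) & is_patient
  )

  list(ct = ct, meta = meta,
       truth = list(factors = tibble::tibble(sample_id = sample_id,
                                             factor_a = fmat[, 1],
                                             factor_b = fmat[, 2],
                                             component_high = comp_high),
                    config = cfg, ref_ct = ref_ct))
}

#' Draw from a univariate Gaussian mixture
#'
#' @param n Number of draws.
#' @param weights Mixture weights (summing to 1).
#' @param means,sds Component parameters.
#' @param seed Integer seed.
#' @return Numeric vector of `n` iid draws; deterministic given `seed`.
#' @export
generate_mixture_scores <- function(n, weights, means, sds, seed = 1) {
  stopifnot(length(weights) == length(means), length(means) == length(sds),
            abs(sum(weights) - 1) < 1e-8, all(weights >= 0), all(sds > 0))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  stats::rnorm(n, means[comp], sds[comp])
}

#' Simulate a two-group score cohort for contrast recovery
#'
#' Generates per-sample scores for two diagnostic groups with a specified
#' true expression fold-difference on the delta-Ct scale
#' (`dct` difference `= -log2(fold)`), with the residual spread calibrated
#' from a target 90% confidence interval: after the ages are drawn, the
#' residual SD is chosen so that the age-adjusted group-contrast standard
#' error of the ANCOVA `score ~ group + age` matches the half-width of the
#' target interval (the design-based contrast variance
#' `c'(X'X)^-1 c` is computed from the realized design matrix, so the
#' group-age collinearity of cohorts with different age distributions is
#' accounted for). Ages are drawn from the validation-cohort distributions;
#' age has no effect on the score, so the adjusted contrast is unconfounded.
#'
#' @param n1,n2 Group sizes.
#' @param groups Character pair of group labels (first group has the higher
#'   expression when `fold > 1`).
#' @param fold True expression ratio group1 / group2.
#' @param ci Length-2 target 90% interval for the ratio, used only to
#'   calibrate the residual SD.
#' @param score Which score column to populate (`"score_a_dct"` or
#'   `"score_b_dct"`); the other is independent noise.
#' @param baseline_dct Mean delta-Ct of the reference (second) group.
#' @param seed Integer seed.
#' @return List with `scores`, `meta`, and `truth` (fold, residual SD).
#' @export
generate_contrast_cohort <- function(n1, n2, groups = c("SLE", "HC"),
                                     fold, ci, score = "score_a_dct",
                                     baseline_dct = 5, seed = 1) {
  stopifnot(length(groups) == 2, fold > 0, length(ci) == 2, all(ci > 0))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  n <- n1 + n2
  diagnosis <- rep(groups, c(n1, n2))
  mu <- ifelse(diagnosis == groups[1], baseline_dct - log2(fold), baseline_dct)
  ref <- ifn_reference_cohort()
  age <- vapply(diagnosis, function(g) {
    row <- ref[ref$diagnosis == g, ]
    if (nrow(row) == 1) stats::rnorm(1, row$age_mean, row$age_sd)
    else stats::rnorm(1, 45, 15)
  }, numeric(1))
  # design-based calibration of the residual SD to the target CI half-width
  X <- cbind(1, as.numeric(diagnosis == groups[1]), age)
  cvar <- solve(crossprod(X))[2, 2] # contrast variance per unit sigma^2
  sd_resid <- (log2(ci[2] / ci[1]) / 2) / stats::qnorm(0.95) / sqrt(cvar)
  vals <- stats::rnorm(n, mu, sd_resid)
  other <- stats::rnorm(n, baseline_dct, sd_resid)
  scores <- tibble::tibble(sample_id = sprintf("C%03d", seq_len(n)))
  scores[[score]] <- vals
  other_col <- setdiff(c("score_a_dct", "score_b_dct"), score)
  scores[[other_col]] <- other
  scores$score_a_expr <- fold_expression(scores$score_a_dct)
  scores$score_b_expr <- fold_expression(scores$score_b_dct)
  meta <- tibble::tibble(sample_id = scores$sample_id, diagnosis = diagnosis,
                         age = pmax(age, 18))
  list(scores = scores, meta = meta,
       truth = list(fold = fold, sd_resid = sd_resid, score = score))
}
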