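#' Classify an effect size on Cohen's partial scale
#'
#' Thresholds 0.01 / 0.06 / 0.14 for small / medium / large; values below
#' 0.01 (including negative partial omega-squared near the null) are
#' negligible.
#'
#' @param value Numeric vector of effect sizes.
#' @return Character vector in `{negligible, small, medium, large}`.
#' @examples
#' classify_effect_size(c(0.005, 0.06, 0.14)) # negligible, medium, large
#' @export
classify_effect_size <- function(value) {
  stopifnot(is.numeric(value))
  cut(value, breaks = c(-Inf, 0.01, 0.06, 0.14, Inf),
      labels = c("negligible", "small", "medium", "large"),
      right = FALSE) |> as.character()
}

# Partial effect sizes for one model term from nested fits.
partial_effects <- function(full, reduced) {
  ss_res <- sum(stats::residuals(full)^2)
  ss_eff <- sum(stats::residuals(reduced)^2) - ss_res
  df_eff <- full$rank - reduced$rank
  n <- length(stats::residuals(full))
  mse <- ss_res / full$df.residual
  eta <- ss_eff / (ss_eff + ss_res)
  omega <- (ss_eff - df_eff * mse) / (ss_eff + (n - df_eff) * mse)
  list(partial_eta_sq = eta, partial_omega_sq = omega)
}

#' Age-adjusted group contrasts as expression ratios
#'
#' Fits the ANCOVA `score_dct ~ group + covariates` on the delta-Ct scale
#' and back-transforms each pairwise group contrast to an expression ratio
#' `2^(-(adjusted mean dct difference))`. Confidence intervals (default
#' 90%) are reported both raw and Tukey-HSD adjusted, together with the
#' Tukey-adjusted p-value over all pairs and partial omega- and eta-squared
#' for the group term.
#'
#' @param scores Score tibble (from [compute_ifn_scores()] or any tibble
#'   with `sample_id` and the score column).
#' @param meta Metadata tibble with `sample_id`, the grouping column
#'   `diagnosis` and the covariates.
#' @param score Score column modelled (default `"score_a_dct"`).
#' @param groups Diagnosis levels compared; all pairwise contrasts among
#'   them are returned, each labeled `"X vs Y"` with ratio = expression in
#'   X relative to Y.
#' @param covariates Covariate column names (default `"age"`; use
#'   `character(0)` for none).
#' @param ci_level Confidence level (default 0.90).
#' @return Tibble: `contrast`, `ratio`, `ci_low`, `ci_high` (raw),
#'   `ci_low_adj`, `ci_high_adj` (Tukey-adjusted), `p_value`, `p_adjusted`,
#'   `partial_omega_sq`, `partial_eta_sq`, `effect_class`.
#' @export
ancova_ratio <- function(scores, meta, score = "score_a_dct",
                         groups = c("SLE", "RA", "HC"),
                         covariates = "age", ci_level = 0.90) {
  d <- dplyr::inner_join(scores, meta, by = "sample_id")
  d <- d[d$diagnosis %in% groups & !is.na(d[[score]]), , drop = FALSE]
  d$group <- factor(d$diagnosis, levels = groups)
  counts <- table(d$group)
  if (length(counts) < 2 || any(counts < 3)) {
    stop("Need >= 2 groups with >= 3 samples each", call. = FALSE)
  }
  if (length(unique(d$group)) < 2) stop("Group is constant", call. = FALSE)

  rhs <- paste(c("group", covariates), collapse = " + ")
  fml <- stats::as.formula(paste(score, "~", rhs))
  fit <- stats::lm(fml, data = d)
  red <- stats::lm(stats::as.formula(
    paste(score, "~", paste(c("1", covariates), collapse = " + "))), data = d)
  eff <- partial_effects(fit, red)

  emm <- emmeans::emmeans(fit, "group")
  prs_adj <- summary(emmeans::contrast(emm, "pairwise", adjust = "tukey"),
                     infer = c(TRUE, TRUE), level = ci_level)
  prs_raw <- summary(emmeans::contrast(emm, "pairwise", adjust = "none"),
                     infer = c(TRUE, TRUE), level = ci_level)

  # contrast "X - Y" on dct scale; expression ratio X/Y = 2^(-estimate)
  lab <- gsub(" - ", " vs ", prs_adj$contrast)
  tibble::tibble(
    contrast = lab,
    ratio = 2^(-prs_raw$estimate),
    ci_low = 2^(-prs_raw$upper.CL),
    ci_high = 2^(-prs_raw$lower.CL),
    ci_low_adj = 2^(-prs_adj$upper.CL),
    ci_high_adj = 2^(-prs_adj$lower.CL),
    p_value = prs_raw$p.value,
    p_adjusted = prs_adj$p.value,
    partial_omega_sq = eff$partial_omega_sq,
    partial_eta_sq = eff$partial_eta_sq,
    effect_class = classify_effect_size(eff$partial_omega_sq)
  )
}

#' Covariate associations with an IFN score
#'
#' Linear regression of a score (delta-Ct scale) on clinical covariates;
#' each term's slope is back-transformed to an expression ratio per unit,
#' `2^(-slope)`, with a confidence interval (default 90%) and a partial
#' omega-squared effect size from dropping the term.
#'
#' @inheritParams ancova_ratio
#' @param terms Model terms of interest (e.g. `"ana_count"`).
#' @param covariates Additional adjustment terms kept in the model but also
#'   reported (e.g. `"age"`).
#' @return Tibble: `term`, `ratio_per_unit`, `ci_low`, `ci_high`,
#'   `p_value`, `partial_omega_sq`, `effect_class`.
#' @export
covariate_association <- function(scores, meta, score = "score_a_dct",
                                  terms, covariates = character(0),
                                  ci_level = 0.90) {
  d <- dplyr::inner_join(scores, meta, by = "sample_id")
  all_terms <- c(terms, covariates)
  missing <- setdiff(all_terms, names(d))
  if (length(missing) > 0) {
    stop("Term(s) absent from metadata: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  d <- d[stats::complete.cases(d[, c(score, all_terms)]), , drop = FALSE]
  fml <- stats::as.formula(paste(score, "~", paste(all_terms, collapse = " + ")))
  fit <- stats::lm(fml, data = d)
  if (any(is.na(stats::coef(fit)))) {
    stop("Rank-deficient design; aliased term(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "),
         call. = FALSE)
  }
  cf <- summary(fit)$coefficients
  ci <- stats::confint(fit, level = ci_level)

  purrr::map_dfr(all_terms, function(tm) {
    # coefficient rows belonging to this term (factors expand to dummies)
    asg <- attr(stats::model.matrix(fit), "assign")
    idx <- which(asg == match(tm, attr(stats::terms(fit), "term.labels")))
    red <- stats::lm(stats::as.formula(
      paste(score, "~", paste(c("1", setdiff(all_terms, tm)), collapse = " + "))),
      data = d)
    eff <- partial_effects(fit, red)
    slope <- unname(stats::coef(fit)[idx[1]])
    tibble::tibble(
      term = tm,
      ratio_per_unit = 2^(-slope),
      ci_low = unname(2^(-ci[idx[1], 2])),
      ci_high = unname(2^(-ci[idx[1], 1])),
      p_value = unname(cf[idx[1], 4]),
      partial_omega_sq = eff$partial_omega_sq,
      effect_class = classify_effect_size(eff$partial_omega_sq)
    )
  })
}

#' Nonparametric two-group contrast on the expression scale
#'
#' Medians and interquartile ranges per group on the `2^(-dct)` scale with
#' a two-sided Mann-Whitney U test. The test is exact (enumeration) when
#' both groups have at most 20 observations and no ties; otherwise the
#' normal approximation with continuity and tie correction is used. Being
#' rank-based, the p-value is identical on the delta-Ct and expression
#' scales.
#'
#' @param values Numeric expression values.
#' @param groups Two-level grouping vector parallel to `values`.
#' @return List with `summary` tibble (group, n, median, iqr), `statistic`
#'   (U for the first group), and `p_value`.
#' @export
nonparametric_contrast <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) != 2) stop("Exactly two groups required", call. = FALSE)
  keep <- !is.na(values) & !is.na(g)
  values <- values[keep]
  g <- droplevels(g[keep])
  ns <- table(g)
  if (any(ns < 2)) stop("Each group needs n >= 2", call. = FALSE)
  x <- values[g == levels(g)[1]]
  y <- values[g == levels(g)[2]]
  exact <- length(x) <= 20 && length(y) <= 20 && !any(duplicated(values))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  list(
    summary = tibble::tibble(
      group = levels(g), n = as.integer(ns),
      median = c(stats::median(x), stats::median(y)),
      iqr = c(stats::IQR(x), stats::IQR(y))
    ),
    statistic = unname(wt$statistic),
    p_value = wt$p.value
  )
}

#' Multiple imputation by predictive mean matching
#'
#' Imputes missing metadata entries `m` times. Continuous variables use
#' predictive mean matching: the variable is regressed on age and both IFN
#' scores (delta-Ct scale) among complete cases, predictions are made for
#' all cases, and each missing entry is filled with the observed value of a
#' donor drawn at random from the `k_neighbours` complete cases closest in
#' predicted value — so every imputed value is an observed value of that
#' variable. Binary (logical) variables are imputed by a Bernoulli draw
#' from a logistic model with the same predictors. Deterministic given
#' `seed`.
#'
#' @param meta Metadata tibble with `sample_id`, `age` and variables to
#'   impute.
#' @param scores Score tibble supplying `score_a_dct` and `score_b_dct`.
#' @param vars Variables to impute (default: all with missing values,
#'   excluding ids and predictors).
#' @param m Number of imputed datasets (default 20).
#' @param k_neighbours Donor pool size (default 10).
#' @param seed Integer seed.
#' @return List of `m` completed metadata tibbles.
#' @export
pmm_impute <- function(meta, scores, vars = NULL, m = 20, k_neighbours = 10,
                       seed = 1) {
  d <- dplyr::inner_join(meta, scores[, c("sample_id", "score_a_dct", "score_b_dct")],
                         by = "sample_id")
  predictors <- c("age", "score_a_dct", "score_b_dct")
  if (is.null(vars)) {
    vars <- setdiff(names(d)[vapply(d, anyNA, logical(1))],
                    c("sample_id", "diagnosis", predictors))
  }
  for (v in vars) {
    frac <- mean(is.na(d[[v]]))
    if (frac >= 0.5) stop("More than 50% missing in ", v, call. = FALSE)
  }
  if (length(vars) == 0 || !anyNA(d[, vars])) {
    return(replicate(m, meta, simplify = FALSE))
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)

  lapply(seq_len(m), function(i) {
    out <- meta
    for (v in vars) {
      miss <- is.na(d[[v]])
      if (!any(miss)) next
      cc <- stats::complete.cases(d[, c(v, predictors)])
      if (!any(cc)) stop("No complete cases to model ", v, call. = FALSE)
      if (is.logical(d[[v]]) ||
          (is.numeric(d[[v]]) && all(d[[v]][!miss] %in% c(0, 1)))) {
        fit <- stats::glm(stats::as.formula(
          paste(v, "~", paste(predictors, collapse = " + "))),
          data = d[cc, ], family = stats::binomial())
        p <- stats::predict(fit, newdata = d[miss, , drop = FALSE],
                            type = "response")
        draw <- stats::rbinom(sum(miss), 1, p)
        out[[v]][miss] <- if (is.logical(d[[v]])) draw == 1 else draw
      } else {
        fit <- stats::lm(stats::as.formula(
          paste(v, "~", paste(predictors, collapse = " + "))),
          data = d[cc, ])
        pred_all <- stats::predict(fit, newdata = d)
        donors_idx <- which(cc)
        for (j in which(miss)) {
          dist <- abs(pred_all[donors_idx] - pred_all[j])
          pool <- donors_idx[order(dist)[seq_len(min(k_neighbours, length(donors_idx)))]]
          out[[v]][j] <- d[[v]][pool[sample.int(length(pool), 1)]]
        }
      }
    }
    out
  })
}

#' Pool estimates across imputations by Rubin's rules
#'
#' The pooled estimate is the mean across imputations; total variance is
#' `W + (1 + 1/m) B` with `W` the mean within-imputation variance and `B`
#' the between-imputation variance; degrees of freedom follow Rubin's
#' small-sample formula. Effect sizes are pooled on the Fisher-z scale
#' (atanh, mean, tanh).
#'
#' @param estimates Per-imputation point estimates.
#' @param variances Per-imputation squared standard errors.
#' @param effect_sizes Optional per-imputation effect sizes in `(-1, 1)`.
#' @return Tibble with `estimate`, `variance`, `se`, `df`,
#'   `between_variance`, `within_variance`, and `effect_size` (NA if not
#'   supplied).
#' @export
pool_rubin <- function(estimates, variances, effect_sizes = NULL) {
  m <- length(estimates)
  stopifnot(m >= 2, length(variances) == m)
  qbar <- mean(estimates)
  wbar <- mean(variances)
  b <- stats::var(estimates)
  total <- wbar + (1 + 1 / m) * b
  df <- if (b > 0) (m - 1) * (1 + wbar / ((1 + 1 / m) * b))^2 else Inf
  es <- if (is.null(effect_sizes)) NA_real_ else tanh(mean(atanh(effect_sizes)))
  tibble::tibble(estimate = qbar, variance = total, se = sqrt(total), df = df,
                 between_variance = b, within_variance = wbar,
                 effect_size = es)
}
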