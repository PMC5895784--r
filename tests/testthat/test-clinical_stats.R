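make_two_group <- function(d1, d2, groups = c("SLE", "HC"), score = "score_a_dct") {
  n <- length(d1) + length(d2)
  scores <- tibble::tibble(sample_id = paste0("s", seq_len(n)))
  scores[[score]] <- c(d1, d2)
  meta <- tibble::tibble(sample_id = scores$sample_id,
                         diagnosis = rep(groups, c(length(d1), length(d2))),
                         age = rep(40, n))
  list(scores = scores, meta = meta)
}

test_that("identical groups give ratio 1 and a negligible effect", {
  set.seed(1)
  v <- rnorm(30, 5)
  tg <- make_two_group(v, v)
  tg$meta$age <- rep(rnorm(30, 40, 10), 2) # same ages in both groups
  cr <- ancova_ratio(tg$scores, tg$meta, groups = c("SLE", "HC"))
  expect_equal(cr$ratio, 1, tolerance = 1e-8)
  expect_lte(cr$partial_omega_sq, 0.01)
  expect_equal(cr$effect_class, "negligible")
})

test_that("without covariates the ratio equals the closed form 2^(-d)", {
  set.seed(2)
  d1 <- rnorm(25, 3)
  d2 <- rnorm(30, 5)
  tg <- make_two_group(d1, d2)
  cr <- ancova_ratio(tg$scores, tg$meta, groups = c("SLE", "HC"),
                     covariates = character(0))
  expect_equal(cr$ratio, 2^(-(mean(d1) - mean(d2))), tolerance = 1e-10)
})

test_that("a zero-weight covariate reproduces the covariate-free closed form", {
  set.seed(3)
  d1 <- rnorm(40, 3)
  d2 <- rnorm(40, 5)
  tg <- make_two_group(d1, d2)
  tg$meta$age <- 40 # constant age carries no weight
  with_cov <- ancova_ratio(tg$scores, tg$meta, groups = c("SLE", "HC"))
  expect_equal(with_cov$ratio, 2^(-(mean(d1) - mean(d2))), tolerance = 1e-10)
})

test_that("Tukey adjustment never reduces p, ratios are shift-equivariant", {
  set.seed(4)
  n <- 90
  scores <- tibble::tibble(sample_id = paste0("s", 1:n),
                           score_a_dct = rnorm(n, rep(c(3, 4, 5), each = 30)))
  meta <- tibble::tibble(sample_id = scores$sample_id,
                         diagnosis = rep(c("SLE", "RA", "HC"), each = 30),
                         age = rnorm(n, 45, 12))
  cr <- ancova_ratio(scores, meta)
  expect_true(all(cr$p_adjusted >= cr$p_value - 1e-12))
  expect_true(all(cr$ci_low <= cr$ratio & cr$ratio <= cr$ci_high))

  shifted <- scores
  sle <- meta$diagnosis == "SLE"
  shifted$score_a_dct[sle] <- shifted$score_a_dct[sle] - 2
  cr2 <- ancova_ratio(shifted, meta)
  for (ctr in c("SLE vs RA", "SLE vs HC")) {
    expect_equal(cr2$ratio[cr2$contrast == ctr],
                 4 * cr$ratio[cr$contrast == ctr], tolerance = 1e-8)
  }
  expect_equal(cr2$ratio[cr2$contrast == "RA vs HC"],
               cr$ratio[cr$contrast == "RA vs HC"], tolerance = 1e-8)
})

test_that("degenerate designs are rejected", {
  tg <- make_two_group(rnorm(10), rnorm(2))
  expect_error(ancova_ratio(tg$scores, tg$meta, groups = c("SLE", "HC")),
               ">= 3 samples")
})

test_that("effect sizes classify on the Cohen partial scale", {
  expect_equal(classify_effect_size(c(0.005, 0.01, 0.059, 0.06, 0.139, 0.14, -0.02)),
               c("negligible", "small", "small", "medium", "medium", "large",
                 "negligible"))
})

test_that("covariate associations: null covariate and exact slope back-transform", {
  set.seed(5)
  n <- 120
  meta <- tibble::tibble(sample_id = paste0("s", 1:n),
                         ana_count = rpois(n, 2),
                         noise_cov = rnorm(n))
  scores <- tibble::tibble(sample_id = meta$sample_id,
                           score_a_dct = 6 - 1 * meta$ana_count + rnorm(n, sd = 1e-6))
  ca <- covariate_association(scores, meta, terms = c("ana_count", "noise_cov"))
  expect_equal(ca$ratio_per_unit[ca$term == "ana_count"], 2, tolerance = 1e-4)
  expect_lt(abs(ca$ratio_per_unit[ca$term == "noise_cov"] - 1), 0.05)
  expect_lt(ca$partial_omega_sq[ca$term == "noise_cov"], 0.01)

  meta$alias <- meta$ana_count * 2
  expect_error(covariate_association(scores, meta, terms = c("ana_count", "alias")),
               "aliased")
})

test_that("Mann-Whitney contrast: null, enumeration tail, rank invariance", {
  set.seed(6)
  v <- rnorm(12)
  same <- nonparametric_contrast(c(v, v), rep(c("a", "b"), each = 12))
  expect_gt(same$p_value, 0.99)

  # disjoint supports, n = 10 vs 10: exact tail is 2 / choose(20, 10)
  x <- 1:10
  y <- 101:110
  res <- nonparametric_contrast(c(x, y), rep(c("a", "b"), each = 10))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 2 / choose(20, 10), tolerance = 1e-12)

  # monotone transform leaves the p-value unchanged
  set.seed(7)
  a <- rnorm(25, 5)
  b <- rnorm(30, 6)
  g <- rep(c("a", "b"), c(25, 30))
  p_dct <- nonparametric_contrast(c(a, b), g)$p_value
  p_expr <- nonparametric_contrast(fold_expression(c(a, b)), g)$p_value
  expect_equal(p_dct, p_expr)

  expect_error(nonparametric_contrast(1:5, c("a", "a", "a", "a", "b")),
               "n >= 2")
})

test_that("PMM imputation: identity without missingness, observed-donor property", {
  set.seed(8)
  n <- 80
  meta <- tibble::tibble(sample_id = paste0("s", 1:n), age = rnorm(n, 45, 10),
                         lymphocyte_count = rlnorm(n, 0.5, 0.3))
  scores <- tibble::tibble(sample_id = meta$sample_id,
                           score_a_dct = rnorm(n, 4), score_b_dct = rnorm(n, 5))
  sets <- pmm_impute(meta, scores, m = 3, seed = 1)
  expect_length(sets, 3)
  expect_identical(sets[[1]], meta)

  miss <- meta
  gone <- sample(n, 15)
  miss$lymphocyte_count[gone] <- NA
  sets2 <- pmm_impute(miss, scores, m = 5, seed = 2)
  observed <- meta$lymphocyte_count[-gone]
  for (s in sets2) {
    expect_no_na(s$lymphocyte_count)
    expect_true(all(s$lymphocyte_count[gone] %in% observed))
  }
  # deterministic given seed
  sets3 <- pmm_impute(miss, scores, m = 5, seed = 2)
  expect_identical(sets2, sets3)
})

test_that("PMM recovers the pre-deletion mean under MCAR missingness", {
  set.seed(9)
  n <- 200
  score_a <- rnorm(n, 4, 1.5)
  v <- 2 + 0.7 * score_a + rnorm(n, sd = sqrt(1 - 0.7^2) * 1.5)
  meta <- tibble::tibble(sample_id = paste0("s", 1:n), age = rnorm(n, 45, 10),
                         marker = v)
  scores <- tibble::tibble(sample_id = meta$sample_id, score_a_dct = score_a,
                           score_b_dct = rnorm(n, 5))
  full_mean <- mean(v)
  miss <- meta
  gone <- sample(n, 40)
  miss$marker[gone] <- NA
  sets <- pmm_impute(miss, scores, m = 20, seed = 3)
  pooled_mean <- mean(vapply(sets, function(s) mean(s$marker), numeric(1)))
  mc_se <- sd(v) / sqrt(n)
  expect_lt(abs(pooled_mean - full_mean), 2 * mc_se)
})

test_that("binary variables are imputed by logistic draws", {
  set.seed(10)
  n <- 120
  score_a <- rnorm(n, 4)
  flag <- runif(n) < plogis(2 - 0.8 * score_a)
  meta <- tibble::tibble(sample_id = paste0("s", 1:n), age = rnorm(n, 45, 10),
                         low_complement = flag)
  scores <- tibble::tibble(sample_id = meta$sample_id, score_a_dct = score_a,
                           score_b_dct = rnorm(n, 5))
  miss <- meta
  miss$low_complement[sample(n, 25)] <- NA
  sets <- pmm_impute(miss, scores, m = 4, seed = 4)
  for (s in sets) {
    expect_type(s$low_complement, "logical")
    expect_no_na(s$low_complement)
  }
})

test_that("Rubin pooling matches hand-worked values", {
  same <- pool_rubin(c(2, 2, 2), c(0.5, 0.5, 0.5))
  expect_equal(same$estimate, 2)
  expect_equal(same$between_variance, 0)
  expect_equal(same$variance, 0.5)

  hand <- pool_rubin(c(1, 3), c(1, 1))
  expect_equal(hand$estimate, 2)
  expect_equal(hand$between_variance, 2)
  expect_equal(hand$variance, 1 + 1.5 * 2)

  es <- pool_rubin(c(1, 3), c(1, 1), effect_sizes = c(0.5, 0.5))
  expect_equal(es$effect_size, 0.5)
})
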