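# --- adequacy diagnostics ---------------------------------------------------

test_that("any correlated pair gives overall KMO exactly 0.5", {
  for (r in c(-0.7, 0.2, 0.9)) {
    R <- matrix(c(1, r, r, 1), 2)
    expect_equal(kmo(R)$overall, 0.5, tolerance = 1e-12)
  }
})

test_that("KMO matches a brute-force partial-correlation oracle", {
  # one-factor matrix, all loadings 0.8
  lam <- rep(0.8, 4)
  R <- tcrossprod(lam) + diag(1 - lam^2)
  # oracle: partial correlation of each pair given the rest via conditional
  # covariance (Schur complement), no precision-matrix shortcut
  p <- ncol(R)
  r2 <- q2 <- 0
  for (i in 1:(p - 1)) {
    for (j in (i + 1):p) {
      rest <- setdiff(1:p, c(i, j))
      S <- R[c(i, j), c(i, j)] -
        R[c(i, j), rest] %*% solve(R[rest, rest]) %*% R[rest, c(i, j)]
      q <- S[1, 2] / sqrt(S[1, 1] * S[2, 2])
      r2 <- r2 + 2 * R[i, j]^2
      q2 <- q2 + 2 * q^2
    }
  }
  expect_equal(kmo(R)$overall, r2 / (r2 + q2), tolerance = 1e-10)
})

test_that("per-variable KMO brackets the overall value on random PD matrices", {
  set.seed(1)
  for (rep in 1:10) {
    X <- matrix(rnorm(200 * 6), 200, 6)
    X[, 1] <- X[, 1] + 0.5 * X[, 2]
    k <- kmo(cor(X))
    expect_gte(max(k$per_variable), k$overall - 1e-12)
    expect_lte(min(k$per_variable), k$overall + 1e-12)
  }
})

test_that("Bartlett sphericity: identity null, df formula, closed-form chi2", {
  b0 <- bartlett_sphericity(diag(5), 50)
  expect_equal(b0$chi2, 0)
  expect_equal(b0$p_value, 1)
  expect_equal(bartlett_sphericity(diag(31) * 0.999 + 0.001, 100)$df, 465)
  # p = 3 equicorrelated rho = 0.5: det = (1-rho)^2 (1+2rho) = 0.5
  R <- matrix(0.5, 3, 3)
  diag(R) <- 1
  b <- bartlett_sphericity(R, 100)
  expect_equal(b$df, 3)
  expect_equal(b$chi2, (99 - 11 / 6) * log(2), tolerance = 1e-10)
})

test_that("SMC matches an independent regression R-squared oracle", {
  R <- matrix(c(1, 0.6, 0.3,
                0.6, 1, 0.5,
                0.3, 0.5, 1), 3)
  s <- smc(R)
  for (i in 1:3) {
    rest <- setdiff(1:3, i)
    r2 <- drop(R[i, rest] %*% solve(R[rest, rest]) %*% R[rest, i])
    expect_equal(unname(s[i]), r2, tolerance = 1e-10)
  }
})

test_that("smc_screen: clean data unflagged, duplicated gene ranked first", {
  set.seed(5)
  m <- matrix(rnorm(600), 200, 3, dimnames = list(NULL, paste0("g", 1:3)))
  scr <- smc_screen(make_dct(m))
  expect_false(scr$flagged)
  expect_true(all(scr$adequacy$smc < 0.2))
  expect_gt(scr$adequacy$determinant, 0.9)

  m2 <- cbind(m, dup = m[, 1] + rnorm(200, sd = 1e-4))
  scr2 <- smc_screen(make_dct(m2))
  expect_true(scr2$flagged)
  expect_equal(scr2$ranking$gene[1:2] %in% c("g1", "dup"), c(TRUE, TRUE))
  expect_gt(det(cor(m2[, scr2$retained])), 1e-5)
})

test_that("adequacy diagnostics are invariant to sample and gene reordering", {
  set.seed(9)
  m <- matrix(rnorm(500), 100, 5, dimnames = list(NULL, paste0("g", 1:5)))
  d1 <- make_dct(m)
  perm <- m[sample(100), sample(5)]
  d2 <- make_dct(perm)
  s1 <- smc_screen(d1)
  s2 <- smc_screen(d2)
  expect_equal(s1$adequacy$kmo_overall, s2$adequacy$kmo_overall)
  expect_equal(s1$adequacy$bartlett_chi2, s2$adequacy$bartlett_chi2)
  expect_equal(s1$adequacy$determinant, s2$adequacy$determinant)
  expect_equal(sort(s1$adequacy$smc), sort(s2$adequacy$smc),
               ignore_attr = TRUE)
})

# --- parallel analysis ------------------------------------------------------

test_that("parallel analysis is deterministic given the seed", {
  set.seed(2)
  m <- matrix(rnorm(150 * 8), 150, 8, dimnames = list(NULL, paste0("g", 1:8)))
  a <- parallel_analysis(m, n_reps = 100, seed = 17)
  b <- parallel_analysis(m, n_reps = 100, seed = 17)
  expect_identical(a, b)
})

test_that("noise data retain no factors under the percentile reference", {
  zero <- vapply(1:30, function(s) {
    set.seed(1000 + s)
    m <- matrix(rnorm(200 * 10), 200, 10)
    parallel_analysis(m, n_reps = 150, seed = s, criterion = "quantile",
                      quantile = 0.99)$n_factors == 0L
  }, logical(1))
  expect_gte(mean(zero), 0.93)
})

test_that("a clear two-factor structure retains at least two factors", {
  L <- cbind(c(rep(0.8, 5), rep(0, 5)), c(rep(0, 5), rep(0.8, 5)))
  hits <- vapply(1:20, function(s) {
    set.seed(2000 + s)
    X <- matrix(rnorm(300 * 2), 300, 2) %*% t(L) +
      matrix(rnorm(300 * 10), 300, 10) %*% diag(sqrt(1 - rowSums(L^2)))
    parallel_analysis(X, n_reps = 150, seed = s)$n_factors >= 2L
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

# --- principal-axis factoring -----------------------------------------------

test_that("PAF recovers an exact one-factor model", {
  lam <- rep(0.8, 4)
  R <- tcrossprod(lam) + diag(1 - lam^2)
  f <- principal_axis_factoring(R, 1)
  expect_lt(max(abs(abs(f$loadings) - 0.8)), 1e-4)
  expect_lt(max(abs(f$communalities - 0.64)), 1e-3)
})

test_that("final reduced eigenvalues are non-increasing and trace-consistent", {
  set.seed(4)
  L <- cbind(c(rep(0.7, 3), rep(0, 3)), c(rep(0, 3), rep(0.7, 3)))
  X <- matrix(rnorm(200 * 2), 200, 2) %*% t(L) +
    matrix(rnorm(200 * 6), 200, 6) %*% diag(sqrt(1 - rowSums(L^2)))
  f <- principal_axis_factoring(cor(X), 2)
  expect_true(all(diff(f$eigenvalues) <= 1e-10))
  expect_equal(sum(f$eigenvalues), sum(f$communalities), tolerance = 1e-8)
})

test_that("PAF recovers a two-block orthogonal design up to sign/permutation", {
  L <- cbind(c(rep(0.7, 4), rep(0, 4)), c(rep(0, 4), rep(0.7, 4)))
  R <- tcrossprod(L) + diag(1 - rowSums(L^2))
  f <- principal_axis_factoring(R, 2, tol = 1e-8)
  # align columns to the generator by absolute correlation
  est <- f$loadings
  if (abs(est[1, 2]) > abs(est[1, 1])) est <- est[, 2:1]
  for (j in 1:2) if (sum(est[, j]) < 0) est[, j] <- -est[, j]
  expect_lt(max(abs(est - L)), 1e-3)
})

# --- promax -----------------------------------------------------------------

test_that("orthogonal simple structure stays orthogonal under promax", {
  L <- cbind(c(rep(0.8, 4), rep(0, 4)), c(rep(0, 4), rep(0.8, 4)))
  rot <- promax_rotation(L)
  expect_lt(abs(rot$phi[1, 2]), 0.02)
  est <- rot$pattern
  if (abs(est[1, 2]) > abs(est[1, 1])) est <- est[, 2:1]
  for (j in 1:2) if (sum(est[, j]) < 0) est[, j] <- -est[, j]
  expect_lt(max(abs(est - L)), 0.02)
})

test_that("structure equals pattern times phi", {
  set.seed(6)
  for (rep in 1:5) {
    A <- matrix(rnorm(24, sd = 0.5), 8, 3)
    rot <- promax_rotation(A)
    expect_lt(max(abs(rot$structure - rot$pattern %*% rot$phi)), 1e-8)
    expect_equal(rot$phi, t(rot$phi))
    expect_equal(diag(rot$phi), rep(1, 3), tolerance = 1e-8)
  }
})

test_that("promax recovers a known inter-factor correlation", {
  L <- cbind(c(rep(0.8, 6), rep(0, 6)), c(rep(0, 6), rep(0.8, 6)))
  Phi <- matrix(c(1, 0.6, 0.6, 1), 2)
  Psi <- 1 - rowSums((L %*% Phi) * L)
  set.seed(8)
  X <- matrix(rnorm(1000 * 2), 1000, 2) %*% chol(Phi) %*% t(L) +
    matrix(rnorm(1000 * 12), 1000, 12) %*% diag(sqrt(Psi))
  f <- principal_axis_factoring(cor(X), 2)
  rot <- promax_rotation(f$loadings)
  expect_lt(abs(abs(rot$phi[1, 2]) - 0.6), 0.05)
})

# --- gene assignment and scores ---------------------------------------------

test_that("published loading values assign, exclude and cross-load as published", {
  P <- rbind(ISG15 = c(0.96, 0.0), CASP1 = c(0.2, 0.3), HERC5 = c(0.43, 0.59),
             CXCL10 = c(0.71, -0.41), LAMP3 = c(0.40, 0.0))
  colnames(P) <- c("A", "B")
  a <- assign_genes(P)
  expect_true("ISG15" %in% a$assignments$A)
  expect_true("CASP1" %in% a$unassigned)
  expect_true("HERC5" %in% a$cross_loaded)
  # signed rule: the -0.41 loading does not cross-load CXCL10
  expect_true("CXCL10" %in% a$assignments$A)
  # ties at exactly the threshold count as loaded
  expect_true("LAMP3" %in% a$assignments$A)
})

test_that("median factor scores follow the censored ranking rule", {
  d <- make_dct(rbind(s1 = c(g1 = 2, g2 = 4, g3 = 9)))
  expect_equal(median_factor_scores(d, list(F = c("g1", "g2", "g3")))$F, 4)
  d2 <- make_dct(rbind(s1 = c(g1 = 2, g2 = NA, g3 = 4)))
  expect_equal(median_factor_scores(d2, list(F = c("g1", "g2", "g3")))$F, 4)
  d3 <- make_dct(rbind(s1 = c(g1 = 7, g2 = 7, g3 = 7)))
  expect_equal(median_factor_scores(d3, list(F = c("g1", "g2", "g3")))$F, 7)
  # majority nondetect -> masked
  d4 <- make_dct(rbind(s1 = c(g1 = 2, g2 = NA, g3 = NA)))
  expect_true(is.na(median_factor_scores(d4, list(F = c("g1", "g2", "g3")))$F))
  expect_error(median_factor_scores(d, list(F = character(0))), "Empty")
})

# --- end-to-end derivation --------------------------------------------------

test_that("derive_factor_solution reports a coherent two-factor solution", {
  sim <- generate_cohort(loading_model_config(seed = 42))
  dct <- compute_delta_ct(sim$ct, "PPIA")
  sol <- derive_factor_solution(dct, n_factors = 2, n_reps = 100, seed = 1)
  expect_s3_class(sol, "ifn_factor_solution")
  expect_equal(sol$n_factors, 2)
  expect_lt(max(abs(sol$structure - sol$pattern %*% sol$phi)), 1e-8)
  expect_true("ISG15" %in% sol$assignments$A)
  expect_true("TAP1" %in% sol$assignments$B)
  expect_true("CASP1" %in% sol$unassigned)
  expect_gt(sol$variance_explained_common, 0.7)
  g <- glance(sol)
  expect_equal(g$bartlett_df, 31 * 30 / 2)
  td <- tidy(sol)
  expect_equal(nrow(td), 31 * 2 * 2)
  expect_s3_class(autoplot(sol), "ggplot")
})

test_that("strongly loaded genes are partitioned correctly across seeds", {
  panel <- ifn_panel()
  strong_a <- panel$gene[panel$score == "A" & panel$loading_a >= 0.5]
  strong_b <- panel$gene[panel$score == "B" & panel$loading_b >= 0.5]
  ok <- vapply(1:20, function(s) {
    sim <- generate_cohort(loading_model_config(seed = 3000 + s))
    m <- cor(dct_wide_for_test(sim$ct))
    f <- principal_axis_factoring(m, 2)
    al <- align_pattern(promax_rotation(f$loadings)$pattern)
    a <- assign_genes(al)
    all(strong_a %in% a$assignments$A) && all(strong_b %in% a$assignments$B) &&
      "CASP1" %in% a$unassigned
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("variance explained is non-decreasing in the factor count", {
  sim <- generate_cohort(loading_model_config(seed = 77))
  m <- cor(dct_wide_for_test(sim$ct))
  ve <- vapply(1:4, function(k) {
    f <- principal_axis_factoring(m, k)
    ev <- f$eigenvalues
    sum(ev[seq_len(k)]) / sum(ev[ev > 0])
  }, numeric(1))
  expect_true(all(diff(ve) > -1e-8))
})
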