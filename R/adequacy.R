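#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' KMO is the ratio of summed squared correlations to summed squared
#' correlations plus summed squared anti-image partial correlations, where
#' the partials come from the inverse correlation matrix:
#' `q_ij = -S_ij / sqrt(S_ii S_jj)` with `S = R^-1`. The per-variable
#' analogue uses the corresponding row sums. At `p = 2` the partial
#' correlation equals the correlation, forcing an overall KMO of exactly 0.5.
#'
#' @param x Correlation matrix, or a numeric data frame / matrix of
#'   observations (correlations are then computed).
#' @return List with `overall` and `per_variable` (named numeric vector),
#'   both in `[0, 1]`.
#' @export
kmo <- function(x) {
  R <- as_corr(x)
  check_corr(R)
  Rinv <- tryCatch(solve(R), error = function(e) {
    stop("Correlation matrix is singular; remove near-collinear variables ",
         "(see smc_screen)", call. = FALSE)
  })
  d <- 1 / sqrt(diag(Rinv))
  Q <- -Rinv * tcrossprod(d) # anti-image partial correlations
  diag(Q) <- 0
  R0 <- R
  diag(R0) <- 0
  r2 <- R0^2
  q2 <- Q^2
  overall <- sum(r2) / (sum(r2) + sum(q2))
  per_variable <- rowSums(r2) / (rowSums(r2) + rowSums(q2))
  names(per_variable) <- rownames(R)
  list(overall = overall, per_variable = per_variable)
}

as_corr <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (nrow(x) == ncol(x) && max(abs(diag(x) - 1)) < 1e-8 &&
      max(abs(x - t(x))) < 1e-8) {
    x
  } else {
    stats::cor(x)
  }
}

#' Bartlett's test of sphericity
#'
#' Tests whether a correlation matrix is the identity:
#' `chi2 = -(n - 1 - (2p + 5)/6) * ln det(R)` on `p(p-1)/2` degrees of
#' freedom. A significant result indicates correlations large enough to
#' support factor analysis.
#'
#' @param x Correlation matrix (or data; see [kmo()]).
#' @param n Number of observations behind the correlations.
#' @return List with `chi2`, `df`, `p_value`.
#' @export
bartlett_sphericity <- function(x, n) {
  R <- as_corr(x)
  check_corr(R)
  p <- ncol(R)
  stopifnot(n > p)
  detR <- det(R)
  if (detR <= 0) stop("Correlation matrix is not positive definite", call. = FALSE)
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * log(detR)
  df <- p * (p - 1) / 2
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Squared multiple correlations
#'
#' `SMC_g = 1 - 1/(R^-1)_gg`, the proportion of each variable's variance
#' explained by all the others. Exactly collinear variables are reported as
#' `SMC = 1` via the pseudo-inverse and flagged.
#'
#' @param x Correlation matrix (or data).
#' @return Named numeric vector of SMCs in `[0, 1]`.
#' @export
smc <- function(x) {
  R <- as_corr(x)
  check_corr(R)
  inv <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(inv)) {
    e <- eigen(R, symmetric = TRUE)
    pos <- e$values > max(e$values) * 1e-10
    inv <- e$vectors[, pos, drop = FALSE] %*%
      (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
    s <- 1 - 1 / diag(inv)
    s[diag(inv) > 1e10] <- 1
    warning("Correlation matrix singular; SMC of collinear variables set to 1",
            call. = FALSE)
  } else {
    s <- 1 - 1 / diag(inv)
  }
  s <- pmin(pmax(s, 0), 1)
  names(s) <- rownames(R)
  s
}

#' Multicollinearity screen on the correlation determinant
#'
#' Computes the full adequacy report (KMO, Bartlett, determinant, SMC) for a
#' complete delta-Ct table and, when the determinant falls below
#' `determinant_floor`, ranks genes by SMC and greedily removes the most
#' predictable gene until the determinant of the remaining correlation
#' matrix exceeds the floor. The screen is advisory: it reports the ranking
#' and the determinant trajectory, and the caller chooses whether to proceed
#' with the full or the reduced gene set.
#'
#' @param dct Complete long delta-Ct tibble (no nondetects).
#' @param determinant_floor Threshold below which multicollinearity is
#'   flagged (default `1e-5`).
#' @return List with `adequacy` (overall KMO, per-gene KMO, Bartlett
#'   statistic/df/p, determinant, SMC), `flagged` (logical), `ranking`
#'   (tibble of genes by descending SMC), `retained` (reduced gene set), and
#'   `trajectory` (tibble: gene removed, determinant after removal).
#' @export
smc_screen <- function(dct, determinant_floor = 1e-5) {
  m <- dct_matrix(dct)
  if (anyNA(m)) stop("smc_screen needs complete data; run impute_nondetects first",
                     call. = FALSE)
  if (ncol(m) < 3) stop("Need at least 3 genes", call. = FALSE)
  R <- stats::cor(m)
  k <- kmo(R)
  b <- bartlett_sphericity(R, nrow(m))
  s <- smc(R)
  adequacy <- list(
    kmo_overall = k$overall, kmo_per_gene = k$per_variable,
    bartlett_chi2 = b$chi2, bartlett_df = b$df, bartlett_p = b$p_value,
    determinant = det(R), smc = s
  )
  ranking <- tibble::tibble(gene = names(sort(s, decreasing = TRUE)),
                            smc = sort(s, decreasing = TRUE))
  retained <- colnames(R)
  removed <- character(0)
  dets <- numeric(0)
  d <- det(R)
  flagged <- d < determinant_floor
  while (d < determinant_floor && length(retained) > 3) {
    si <- smc(R[retained, retained, drop = FALSE])
    drop_gene <- names(which.max(si))
    retained <- setdiff(retained, drop_gene)
    d <- det(R[retained, retained, drop = FALSE])
    removed <- c(removed, drop_gene)
    dets <- c(dets, d)
  }
  list(adequacy = adequacy, flagged = flagged, ranking = ranking,
       retained = retained,
       trajectory = tibble::tibble(removed = removed, determinant = dets))
}
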