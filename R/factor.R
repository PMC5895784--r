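#' Horn's parallel analysis
#'
#' Compares the observed eigenvalues of the correlation matrix with
#' eigenvalues of `n_reps` simulated datasets of iid standard-normal
#' deviates of identical shape. The number of factors retained is the number
#' of leading ranks at which the observed eigenvalue exceeds the reference
#' (the mean simulated eigenvalue of the same rank by default; a quantile,
#' e.g. the 95th percentile, optionally). Counting stops at the first rank
#' that fails. Deterministic given `seed`.
#'
#' @param dct Complete long delta-Ct tibble, or a numeric samples-by-genes
#'   matrix.
#' @param n_reps Monte-Carlo replications (default 1000).
#' @param seed Integer seed.
#' @param criterion `"mean"` (default) or `"quantile"`.
#' @param quantile Reference quantile when `criterion = "quantile"`.
#' @return List with `n_factors`, `observed` eigenvalues and `reference`
#'   eigenvalues.
#' @export
parallel_analysis <- function(dct, n_reps = 1000, seed = 1,
                              criterion = c("mean", "quantile"),
                              quantile = 0.95) {
  criterion <- match.arg(criterion)
  m <- if (is.matrix(dct)) dct else dct_matrix(dct)
  if (anyNA(m)) stop("parallel_analysis needs complete data", call. = FALSE)
  n <- nrow(m)
  p <- ncol(m)
  stopifnot(n >= 10, n_reps >= 100)
  obs <- eigen(stats::cor(m), symmetric = TRUE, only.values = TRUE)$values
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  sims <- matrix(0, p, n_reps)
  for (r in seq_len(n_reps)) {
    sims[, r] <- eigen(stats::cor(matrix(stats::rnorm(n * p), n, p)),
                       symmetric = TRUE, only.values = TRUE)$values
  }
  ref <- if (criterion == "mean") rowMeans(sims)
         else apply(sims, 1, stats::quantile, probs = quantile)
  k <- 0L
  for (i in seq_len(p)) {
    if (obs[i] > ref[i]) k <- k + 1L else break
  }
  list(n_factors = k, observed = obs, reference = ref)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Iterated principal-axis factoring
#'
#' Extracts `n_factors` common factors from a correlation matrix by the
#' principal-axis method: communalities are initialized with squared
#' multiple correlations, placed on the diagonal of the reduced correlation
#' matrix, which is eigendecomposed; loadings are the leading eigenvectors
#' scaled by the square root of their eigenvalues, and communalities are
#' updated from the loadings until the largest change falls below `tol`.
#' Heywood cases (communality above 1) are clamped to `1 - 1e-6` with a
#' warning.
#'
#' @param corr Correlation matrix (or data; correlations are computed).
#' @param n_factors Number of factors, `1 <= n_factors < p`.
#' @param max_iter,tol Convergence control (defaults 100, 1e-4).
#' @return List with `loadings` (p x n_factors, unrotated), `eigenvalues`
#'   (of the final reduced matrix), `initial_eigenvalues` (SMC-reduced,
#'   first pass), `communalities`, `iterations`, `converged`.
#' @export
principal_axis_factoring <- function(corr, n_factors, max_iter = 100, tol = 1e-4) {
  R <- as_corr(corr)
  check_corr(R)
  p <- ncol(R)
  stopifnot(n_factors >= 1, n_factors < p)
  h <- smc(R)
  Rr <- R
  diag(Rr) <- h
  initial_eigenvalues <- eigen(Rr, symmetric = TRUE, only.values = TRUE)$values
  heywood <- FALSE
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    Rr <- R
    diag(Rr) <- h
    e <- eigen(Rr, symmetric = TRUE)
    ev <- pmax(e$values[seq_len(n_factors)], 0)
    L <- e$vectors[, seq_len(n_factors), drop = FALSE] %*%
      diag(sqrt(ev), n_factors)
    h_new <- rowSums(L^2)
    if (any(h_new > 1)) {
      heywood <- TRUE
      h_new <- pmin(h_new, 1 - 1e-6)
    }
    delta <- max(abs(h_new - h))
    h <- h_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    cnd <- structure(
      class = c("ifnscore_paf_nonconvergence", "error", "condition"),
      list(message = sprintf(
        "Principal-axis factoring did not converge in %d iterations (last max communality change %.2e)",
        max_iter, delta),
        call = sys.call(-1), loadings = L, communalities = h))
    stop(cnd)
  }
  if (heywood) {
    warning("Heywood case: communalities clamped to 1 - 1e-6", call. = FALSE)
  }
  Rr <- R
  diag(Rr) <- h
  e <- eigen(Rr, symmetric = TRUE)
  ev <- pmax(e$values[seq_len(n_factors)], 0)
  L <- e$vectors[, seq_len(n_factors), drop = FALSE] %*% diag(sqrt(ev), n_factors)
  rownames(L) <- rownames(R)
  names(h) <- rownames(R)
  list(loadings = L, eigenvalues = e$values,
       initial_eigenvalues = initial_eigenvalues,
       communalities = h, iterations = iter, converged = converged)
}

kaiser_varimax <- function(A) {
  if (ncol(A) < 2) return(A)
  h <- sqrt(rowSums(A^2))
  hs <- ifelse(h < 1e-8, 1, h) # guard zero-communality rows
  An <- A / hs
  v <- stats::varimax(An, normalize = FALSE)
  unclass(v$loadings) * hs
}

#' Promax (oblique) rotation
#'
#' Varimax rotation with Kaiser row normalization, followed by the promax
#' procrustean transform: the varimax loadings are raised elementwise to
#' power `kappa` (sign preserved) to sharpen simple structure, the oblique
#' transformation is obtained by least-squares regression onto this target
#' and column-normalized, giving the pattern matrix `P = A %*% U`, the
#' factor correlation `Phi = solve(t(U) %*% U)` and the structure matrix
#' `S = P %*% Phi`.
#'
#' @param loadings Unrotated loading matrix with at least 2 columns.
#' @param kappa Promax power (default 4).
#' @return List with `pattern`, `structure`, `phi`.
#' @export
promax_rotation <- function(loadings, kappa = 4) {
  A <- as.matrix(loadings)
  if (ncol(A) < 2) stop("Promax rotation needs at least 2 factors", call. = FALSE)
  Av <- kaiser_varimax(A)
  Q <- Av * abs(Av)^(kappa - 1)
  AtA <- crossprod(Av)
  if (rcond(AtA) < 1e-12) stop("Singular target regression in promax", call. = FALSE)
  U <- solve(AtA, crossprod(Av, Q))
  d <- diag(solve(crossprod(U)))
  U <- U %*% diag(sqrt(d), ncol(U))
  pattern <- Av %*% U
  phi <- solve(crossprod(U))
  phi <- (phi + t(phi)) / 2
  dimnames(pattern) <- dimnames(A)
  structure_ <- pattern %*% phi
  list(pattern = pattern, structure = structure_, phi = phi)
}

#' Assign genes to factors by loading threshold
#'
#' A gene is assigned to the factor on which its signed pattern loading is
#' at least `threshold`, provided it reaches the threshold on exactly one
#' factor; genes at or above the threshold on two or more factors are
#' cross-loaded and excluded; genes below the threshold everywhere are
#' unassigned. Signed (not absolute) loadings are used: a large negative
#' loading does not assign a gene.
#'
#' @param pattern Pattern matrix (genes x factors) with row and column names.
#' @param threshold Loading threshold (default 0.4; ties count as loaded).
#' @return List with `assignments` (factor name -> gene vector),
#'   `cross_loaded`, `unassigned`, and `table` (tibble gene/status/factor).
#' @export
assign_genes <- function(pattern, threshold = 0.4) {
  P <- as.matrix(pattern)
  if (is.null(rownames(P))) rownames(P) <- paste0("g", seq_len(nrow(P)))
  if (is.null(colnames(P))) colnames(P) <- paste0("F", seq_len(ncol(P)))
  hit <- P >= threshold
  nhit <- rowSums(hit)
  status <- ifelse(nhit == 0, "unassigned",
                   ifelse(nhit == 1, "assigned", "cross_loaded"))
  fac <- rep(NA_character_, nrow(P))
  fac[nhit == 1] <- colnames(P)[apply(hit[nhit == 1, , drop = FALSE], 1, which)]
  assignments <- lapply(stats::setNames(colnames(P), colnames(P)),
                        function(f) rownames(P)[!is.na(fac) & fac == f])
  list(assignments = assignments,
       cross_loaded = rownames(P)[status == "cross_loaded"],
       unassigned = rownames(P)[status == "unassigned"],
       table = tibble::tibble(gene = rownames(P), status = status, factor = fac))
}

#' Median delta-Ct factor scores
#'
#' The score of a sample on a factor is the median delta-Ct over the genes
#' assigned to that factor, with nondetects ranked above every detected
#' delta-Ct (they correspond to lower expression). The score is masked (NA)
#' whenever the median order statistic is itself censored, which for
#' odd-sized gene sets means more than half the genes are nondetect.
#'
#' @param dct Long delta-Ct tibble.
#' @param assignments Named list, factor name -> character vector of genes.
#' @return Tibble `sample_id` plus one column per factor.
#' @export
median_factor_scores <- function(dct, assignments) {
  if (any(lengths(assignments) == 0)) {
    stop("Empty gene list for factor(s): ",
         paste(names(assignments)[lengths(assignments) == 0], collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(unlist(assignments), unique(dct$gene))
  if (length(missing) > 0) {
    stop("Assigned gene(s) absent from data: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  nd <- if ("nondetect" %in% names(dct)) dct$nondetect else rep(FALSE, nrow(dct))
  samples <- unique(dct$sample_id)
  out <- tibble::tibble(sample_id = samples)
  for (f in names(assignments)) {
    sub <- dct$gene %in% assignments[[f]]
    vals <- split(dct$dct[sub], factor(dct$sample_id[sub], levels = samples))
    nds <- split(nd[sub], factor(dct$sample_id[sub], levels = samples))
    out[[f]] <- unname(mapply(censored_median, vals, nds))
  }
  out
}

#' Derive a full factor solution from a complete delta-Ct table
#'
#' The end-to-end derivation: adequacy diagnostics (KMO, Bartlett,
#' determinant, SMC), parallel analysis for the maximum factor count,
#' candidate principal-axis solutions for `k = 1..k_max` with their variance
#' explained and cross-loading counts, selection of the simplest adequate
#' solution, promax rotation, threshold assignment and median factor scores.
#'
#' The selector takes parallel analysis as an upper bound and prefers the
#' smallest `k` whose common-variance proportion reaches
#' `variance_target` (default 0.80); among candidates it reports
#' cross-loaded gene counts so a simpler, less cross-loaded solution can be
#' chosen. `n_factors` overrides selection.
#'
#' Factor order and sign are fixed so that, when `anchor_gene` is present,
#' the factor loading it most strongly comes first (named `A`) and each
#' factor's dominant loading is positive.
#'
#' @param dct Complete long delta-Ct tibble.
#' @param n_factors Optional fixed number of factors.
#' @param n_reps,seed Parallel-analysis control.
#' @param kappa Promax power.
#' @param threshold Assignment loading threshold.
#' @param variance_target Common-variance proportion the selected solution
#'   must reach.
#' @param anchor_gene Gene anchoring factor 1 (default `"ISG15"`; ignored if
#'   absent).
#' @return An object of class `ifn_factor_solution`: the rotated solution
#'   (pattern, structure, phi, communalities), diagnostics, candidate table,
#'   gene assignments and per-sample median scores.
#' @export
derive_factor_solution <- function(dct, n_factors = NULL, n_reps = 1000,
                                   seed = 1, kappa = 4, threshold = 0.4,
                                   variance_target = 0.80,
                                   anchor_gene = "ISG15") {
  m <- dct_matrix(dct)
  if (anyNA(m)) stop("derive_factor_solution needs complete data", call. = FALSE)
  R <- stats::cor(m)
  n <- nrow(m)
  p <- ncol(m)

  k_kmo <- kmo(R)
  bart <- bartlett_sphericity(R, n)
  adequacy <- list(kmo_overall = k_kmo$overall, kmo_per_gene = k_kmo$per_variable,
                   bartlett_chi2 = bart$chi2, bartlett_df = bart$df,
                   bartlett_p = bart$p_value, determinant = det(R),
                   smc = smc(R))

  pa <- parallel_analysis(m, n_reps = n_reps, seed = seed)
  k_max <- max(pa$n_factors, if (is.null(n_factors)) 2 else n_factors, 2)

  candidates <- purrr::map_dfr(seq_len(k_max), function(k) {
    f <- tryCatch(principal_axis_factoring(R, k), error = function(e) NULL)
    if (is.null(f)) {
      return(tibble::tibble(k = k, variance_common = NA_real_,
                            variance_total = NA_real_, cross_loaded = NA_integer_))
    }
    ev <- f$eigenvalues
    vc <- sum(ev[seq_len(k)]) / sum(ev[ev > 0])
    vt <- sum(ev[seq_len(k)]) / p
    nx <- if (k >= 2) {
      length(assign_genes(promax_rotation(f$loadings, kappa)$pattern,
                          threshold)$cross_loaded)
    } else 0L
    tibble::tibble(k = k, variance_common = vc, variance_total = vt,
                   cross_loaded = nx)
  })

  if (is.null(n_factors)) {
    ok <- which(!is.na(candidates$variance_common) &
                  candidates$variance_common >= variance_target)
    n_factors <- if (length(ok) > 0) min(ok) else k_max
  }

  fit <- principal_axis_factoring(R, n_factors)
  if (n_factors >= 2) {
    rot <- promax_rotation(fit$loadings, kappa = kappa)
    pattern <- rot$pattern
    phi <- rot$phi
  } else {
    pattern <- fit$loadings
    phi <- matrix(1, 1, 1)
  }

  # order/sign convention
  ord <- order(colSums(pattern^2), decreasing = TRUE)
  if (!is.null(anchor_gene) && anchor_gene %in% rownames(pattern) &&
      ncol(pattern) >= 2) {
    anchor_f <- which.max(abs(pattern[anchor_gene, ]))
    ord <- c(anchor_f, setdiff(ord, anchor_f))
  }
  pattern <- pattern[, ord, drop = FALSE]
  phi <- phi[ord, ord, drop = FALSE]
  for (j in seq_len(ncol(pattern))) {
    if (pattern[which.max(abs(pattern[, j])), j] < 0) {
      pattern[, j] <- -pattern[, j]
      phi[j, ] <- -phi[j, ]
      phi[, j] <- -phi[, j]
    }
  }
  colnames(pattern) <- c("A", "B", paste0("F", seq_len(max(0, ncol(pattern) - 2)) + 2))[seq_len(ncol(pattern))]
  dimnames(phi) <- list(colnames(pattern), colnames(pattern))
  structure_ <- pattern %*% phi

  asg <- assign_genes(pattern, threshold)
  scores <- median_factor_scores(dct, asg$assignments[lengths(asg$assignments) > 0])

  ev <- fit$eigenvalues
  out <- list(
    n_factors = n_factors,
    eigenvalues = fit$initial_eigenvalues,
    pattern = pattern, structure = structure_, phi = phi,
    communalities = fit$communalities,
    variance_explained_common = sum(ev[seq_len(n_factors)]) / sum(ev[ev > 0]),
    variance_explained_total = sum(ev[seq_len(n_factors)]) / p,
    assignments = asg$assignments, cross_loaded = asg$cross_loaded,
    unassigned = asg$unassigned,
    adequacy = adequacy, parallel = pa, candidates = candidates,
    scores = scores, n = n, threshold = threshold, kappa = kappa
  )
  class(out) <- "ifn_factor_solution"
  out
}

#' @export
print.ifn_factor_solution <- function(x, ...) {
  cat("Factor solution:", x$n_factors, "factors from", length(x$communalities),
      "genes,", x$n, "samples\n")
  cat(sprintf("  Common variance explained: %.1f%% (%.1f%% of total)\n",
              100 * x$variance_explained_common, 100 * x$variance_explained_total))
  if (x$n_factors >= 2) {
    cat(sprintf("  Factor correlation (A,B): %.2f\n", x$phi[1, 2]))
  }
  cat(sprintf("  KMO %.2f | Bartlett X2(%d) = %.1f | det(R) = %.2g\n",
              x$adequacy$kmo_overall, x$adequacy$bartlett_df,
              x$adequacy$bartlett_chi2, x$adequacy$determinant))
  for (f in names(x$assignments)) {
    cat("  ", f, ": ", paste(x$assignments[[f]], collapse = ", "), "\n", sep = "")
  }
  if (length(x$cross_loaded) > 0) {
    cat("  cross-loaded: ", paste(x$cross_loaded, collapse = ", "), "\n", sep = "")
  }
  if (length(x$unassigned) > 0) {
    cat("  unassigned: ", paste(x$unassigned, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @method tidy ifn_factor_solution
#' @export
tidy.ifn_factor_solution <- function(x, ...) {
  long <- function(m, what) {
    tibble::tibble(gene = rep(rownames(m), ncol(m)),
                   factor = rep(colnames(m), each = nrow(m)),
                   loading = as.vector(m), matrix = what)
  }
  dplyr::bind_rows(long(x$pattern, "pattern"), long(x$structure, "structure"))
}

#' @method glance ifn_factor_solution
#' @export
glance.ifn_factor_solution <- function(x, ...) {
  tibble::tibble(
    n_factors = x$n_factors, n = x$n,
    variance_explained_common = x$variance_explained_common,
    variance_explained_total = x$variance_explained_total,
    phi_ab = if (x$n_factors >= 2) x$phi[1, 2] else NA_real_,
    kmo_overall = x$adequacy$kmo_overall,
    bartlett_chi2 = x$adequacy$bartlett_chi2,
    bartlett_df = x$adequacy$bartlett_df,
    determinant = x$adequacy$determinant,
    n_cross_loaded = length(x$cross_loaded),
    n_unassigned = length(x$unassigned)
  )
}

#' Loading heatmap for a factor solution
#'
#' @param object An `ifn_factor_solution`.
#' @param ... Unused.
#' @return A ggplot object: genes by factors, fill = pattern loading.
#' @method autoplot ifn_factor_solution
#' @export
autoplot.ifn_factor_solution <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$matrix == "pattern", ]
  d$gene <- factor(d$gene, levels = rev(rownames(object$pattern)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$factor, y = .data$gene,
                                  fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$loading)),
                       size = 2.7) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = "Factor", y = NULL, fill = "Pattern\nloading") +
    ggplot2::theme_minimal()
}
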