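#' Fit a univariate Gaussian mixture by EM
#'
#' Fits a `k`-component normal mixture with unequal variances to reflected
#' delta-Ct values (larger = higher expression). EM runs from `n_init`
#' k-means++-style starts to convergence (log-likelihood change below `tol`
#' or `max_iter` iterations); the best run is kept. The log-likelihood is
#' non-decreasing across iterations. Components whose standard deviation
#' collapses below `1e-6` times the data SD trigger a restart; if every
#' start degenerates, an error is raised.
#'
#' @param values Numeric vector (finite; NAs removed with a message).
#' @param k Number of components (`n >= 5k`).
#' @param seed Integer seed (initialization only; fit is deterministic given
#'   it).
#' @param n_init Number of random starts (default 20).
#' @param max_iter,tol EM control (defaults 500, 1e-8).
#' @return An `ifn_mixture` object: `k`, `weights`, `means`, `sds`
#'   (ascending by mean), `loglik`, `aic`, `bic`, `posteriors`, `n`,
#'   `data`, and the per-iteration `loglik_trace` of the winning run.
#' @export
fit_mixture <- function(values, k, seed = 1, n_init = 20, max_iter = 500,
                        tol = 1e-8) {
  x <- values[!is.na(values)]
  if (length(x) < length(values)) {
    message(length(values) - length(x), " masked value(s) excluded from mixture fit")
  }
  stopifnot(all(is.finite(x)), k >= 1, length(x) >= 5 * k)
  n <- length(x)

  if (k == 1) {
    mu <- mean(x)
    sd1 <- sqrt(mean((x - mu)^2))
    ll <- sum(stats::dnorm(x, mu, sd1, log = TRUE))
    return(new_mixture(k, 1, mu, sd1, ll, matrix(1, n, 1), x, ll))
  }

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  sd_floor <- 1e-6 * stats::sd(x)
  best <- NULL
  for (init in seq_len(n_init)) {
    centers <- kmeanspp_centers(x, k)
    fit <- em_gaussian(x, centers, max_iter, tol, sd_floor)
    if (is.null(fit)) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) {
    stop("All EM starts produced degenerate components", call. = FALSE)
  }
  ord <- order(best$means)
  new_mixture(k, best$weights[ord], best$means[ord], best$sds[ord],
              best$loglik, best$post[, ord, drop = FALSE], x,
              best$trace)
}

new_mixture <- function(k, w, mu, s, ll, post, x, trace) {
  n <- length(x)
  npar <- 3 * k - 1
  out <- list(k = k, weights = w, means = mu, sds = s, loglik = ll,
              aic = 2 * npar - 2 * ll, bic = npar * log(n) - 2 * ll,
              posteriors = post, n = n, data = x, loglik_trace = trace)
  class(out) <- "ifn_mixture"
  out
}

kmeanspp_centers <- function(x, k) {
  centers <- numeric(k)
  centers[1] <- sample(x, 1)
  for (j in seq_len(k)[-1]) {
    d2 <- vapply(x, function(v) min((v - centers[seq_len(j - 1)])^2), numeric(1))
    if (sum(d2) <= 0) {
      centers[j] <- sample(x, 1)
    } else {
      centers[j] <- x[sample.int(length(x), 1, prob = d2)]
    }
  }
  centers
}

em_gaussian <- function(x, centers, max_iter, tol, sd_floor) {
  n <- length(x)
  k <- length(centers)
  mu <- centers
  s <- rep(stats::sd(x) / k, k)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  trace <- numeric(0)
  trace <- numeric(max_iter)
  logd <- matrix(0, n, k)
  for (iter in seq_len(max_iter)) {
    for (j in seq_len(k)) {
      logd[, j] <- log(w[j]) - log(s[j]) - 0.5 * ((x - mu[j]) / s[j])^2
    }
    m <- logd[, 1]
    for (j in seq_len(k)[-1]) m <- pmax(m, logd[, j])
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(lse) - n * 0.5 * log(2 * pi)
    trace[iter] <- ll
    post <- exp(logd - lse)
    nk <- colSums(post)
    if (any(nk < 1e-10)) return(NULL)
    w <- nk / n
    mu <- colSums(post * x) / nk
    for (j in seq_len(k)) s[j] <- sqrt(sum(post[, j] * (x - mu[j])^2) / nk[j])
    if (any(s < sd_floor)) return(NULL)
    if (is.finite(ll_old) && ll - ll_old < tol) break
    ll_old <- ll
  }
  trace <- trace[seq_len(iter)]
  list(weights = w, means = mu, sds = s, loglik = ll, post = post, trace = trace)
}

#' Select the number of mixture components
#'
#' Fits mixtures with `k = 1..k_max` and returns the fit minimizing the
#' chosen information criterion; both AIC and BIC are reported for every
#' `k` in the attached criterion table.
#'
#' @inheritParams fit_mixture
#' @param k_max Largest component count tried (default 4).
#' @param criterion `"bic"` (default) or `"aic"`.
#' @return The winning `ifn_mixture`, with a `criteria` tibble
#'   (`k`, `loglik`, `aic`, `bic`) attached.
#' @export
select_components <- function(values, k_max = 4, criterion = c("bic", "aic"),
                              seed = 1, n_init = 20) {
  criterion <- match.arg(criterion)
  fits <- lapply(seq_len(k_max), function(k) {
    tryCatch(fit_mixture(values, k, seed = seed + k, n_init = n_init),
             error = function(e) NULL)
  })
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (length(fits) == 0) stop("No mixture could be fitted", call. = FALSE)
  crit <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(k = f$k, loglik = f$loglik, aic = f$aic, bic = f$bic)
  })
  best <- fits[[which.min(vapply(fits, function(f) f[[criterion]], numeric(1)))]]
  best$criteria <- crit
  best$criterion <- criterion
  best
}

#' Classify samples as IFN-high or IFN-low
#'
#' For a two-component fit on the reflected delta-Ct scale, the component
#' with the higher mean (higher expression) is "high". Each sample is
#' labeled by its maximum posterior probability; exact posterior ties go to
#' "low" (conservative).
#'
#' @param fit An `ifn_mixture` with `k = 2`.
#' @return List with `labels` tibble (`value`, `label`, `posterior` = max
#'   posterior), `proportion_high`, `mean_membership` (average max
#'   posterior), and the `fit`.
#' @export
classify_high_low <- function(fit) {
  if (!inherits(fit, "ifn_mixture")) stop("Not a mixture fit", call. = FALSE)
  if (fit$k != 2) {
    stop("classify_high_low needs a 2-component fit; use select_components ",
         "to choose k", call. = FALSE)
  }
  hi <- which.max(fit$means) # components sorted ascending, so hi = 2
  p_hi <- fit$posteriors[, hi]
  label <- ifelse(p_hi > 0.5, "high", "low") # ties (exactly 0.5) -> low
  labels <- tibble::tibble(value = fit$data, label = label,
                           posterior = pmax(p_hi, 1 - p_hi))
  list(labels = labels,
       proportion_high = mean(label == "high"),
       mean_membership = mean(labels$posterior),
       fit = fit)
}

#' Standardized separation of a two-component mixture
#'
#' `|mu1 - mu2| / sqrt((sd1^2 + sd2^2)/2)`, the bimodality index used to
#' rank genes.
#'
#' @param fit An `ifn_mixture` with `k = 2`.
#' @return Numeric separation in pooled standard deviations.
#' @export
separation_index <- function(fit) {
  stopifnot(inherits(fit, "ifn_mixture"), fit$k == 2)
  abs(diff(fit$means)) / sqrt(mean(fit$sds^2))
}

#' Compare two high/low classifiers
#'
#' Cross-tabulates the labels of two classifications of the same samples
#' (e.g. a score-based and a single-gene classifier) and reports each
#' classifier's proportion-high, mean membership probability and separation
#' index, plus the label concordance.
#'
#' @param score_cls,gene_cls Results of [classify_high_low()], fitted on the
#'   same samples in the same order.
#' @return List with `summary` tibble (one row per classifier),
#'   `concordance`, and `cross_tab`.
#' @export
compare_classifiers <- function(score_cls, gene_cls) {
  a <- score_cls$labels
  b <- gene_cls$labels
  if (nrow(a) != nrow(b)) stop("Classifier sample sets differ", call. = FALSE)
  summary <- tibble::tibble(
    classifier = c("score", "gene"),
    proportion_high = c(score_cls$proportion_high, gene_cls$proportion_high),
    mean_membership = c(score_cls$mean_membership, gene_cls$mean_membership),
    separation = c(separation_index(score_cls$fit), separation_index(gene_cls$fit))
  )
  list(summary = summary,
       concordance = mean(a$label == b$label),
       cross_tab = table(score = a$label, gene = b$label))
}

#' Rank genes by bimodality
#'
#' Fits a 1..`k_max` component mixture to each gene's reflected delta-Ct
#' values (masked values excluded) and ranks genes by the standardized
#' separation of their two-component fit, flagging whether BIC prefers two
#' or more components over one.
#'
#' @param dct Long delta-Ct tibble.
#' @param genes Genes to rank (default: all in `dct`).
#' @param seed Seed for mixture initialization.
#' @param k_max Passed to [select_components()].
#' @return Tibble `gene`, `separation`, `bic_prefers_mixture`, sorted by
#'   descending separation.
#' @export
rank_gene_bimodality <- function(dct, genes = unique(dct$gene), seed = 1,
                                 k_max = 2) {
  purrr::map_dfr(genes, function(g) {
    v <- dct$dct[dct$gene == g & !dct$nondetect]
    f2 <- tryCatch(fit_mixture(-v, 2, seed = seed), error = function(e) NULL)
    f1 <- fit_mixture(-v, 1)
    tibble::tibble(
      gene = g,
      separation = if (is.null(f2)) NA_real_ else separation_index(f2),
      bic_prefers_mixture = !is.null(f2) && f2$bic < f1$bic
    )
  }) |> dplyr::arrange(dplyr::desc(.data$separation))
}

#' @export
print.ifn_mixture <- function(x, ...) {
  cat("Gaussian mixture, k =", x$k, " n =", x$n, "\n")
  print(round(tibble::tibble(weight = x$weights, mean = x$means, sd = x$sds), 3))
  cat(sprintf("loglik %.2f | AIC %.1f | BIC %.1f\n", x$loglik, x$aic, x$bic))
  invisible(x)
}

#' @method tidy ifn_mixture
#' @export
tidy.ifn_mixture <- function(x, ...) {
  tibble::tibble(component = seq_len(x$k), weight = x$weights,
                 mean = x$means, sd = x$sds)
}

#' @method glance ifn_mixture
#' @export
glance.ifn_mixture <- function(x, ...) {
  tibble::tibble(k = x$k, n = x$n, loglik = x$loglik, aic = x$aic, bic = x$bic)
}

#' Histogram with fitted mixture densities
#'
#' Reproduces the usual bimodality display: histogram of reflected delta-Ct
#' values overlaid with the weighted component densities (solid line =
#' high-expression component, dashed = low).
#'
#' @param object An `ifn_mixture`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ifn_mixture
#' @export
autoplot.ifn_mixture <- function(object, bins = 30, ...) {
  d <- tibble::tibble(value = object$data)
  grid <- seq(min(object$data), max(object$data), length.out = 300)
  hi <- which.max(object$means)
  dens <- purrr::map_dfr(seq_len(object$k), function(j) {
    tibble::tibble(value = grid,
                   density = object$weights[j] *
                     stats::dnorm(grid, object$means[j], object$sds[j]),
                   component = if (j == hi && object$k > 1) "high" else "low")
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey85", colour = "grey60") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(y = .data$density, group = .data$component,
                                    linetype = .data$component)) +
    ggplot2::scale_linetype_manual(values = c(high = "solid", low = "dashed")) +
    ggplot2::labs(x = "Reflected ΔCt", y = "Density", linetype = "Component") +
    ggplot2::theme_minimal()
}
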