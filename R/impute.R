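# Conditional mean of N(mu, sigma^2) truncated to (bound, Inf).
truncated_normal_mean <- function(mu, sigma, bound) {
  a <- (bound - mu) / sigma
  # Mills ratio; stable for large a via log tail probability
  log_tail <- stats::pnorm(a, lower.tail = FALSE, log.p = TRUE)
  mu + sigma * exp(stats::dnorm(a, log = TRUE) - log_tail)
}

# EM for a normal model with right-censored observations.
# y: detected values; bounds: censoring bounds of the censored observations.
censored_normal_em <- function(y, bounds, max_iter = 200, tol = 1e-6) {
  mu <- mean(y)
  sigma <- stats::sd(y)
  if (!is.finite(sigma) || sigma < 1e-8) sigma <- 1e-8
  n <- length(y) + length(bounds)
  for (iter in seq_len(max_iter)) {
    a <- (bounds - mu) / sigma
    log_tail <- stats::pnorm(a, lower.tail = FALSE, log.p = TRUE)
    lambda <- exp(stats::dnorm(a, log = TRUE) - log_tail) # Mills ratio
    m1 <- mu + sigma * lambda                              # E[X | X > c]
    m2 <- mu^2 + sigma^2 + sigma * (bounds + mu) * lambda  # E[X^2 | X > c]
    mu_new <- (sum(y) + sum(m1)) / n
    ss <- sum((y - mu_new)^2) + sum(m2 - 2 * mu_new * m1 + mu_new^2)
    sigma_new <- sqrt(max(ss / n, 1e-12))
    done <- max(abs(mu_new - mu), abs(sigma_new - sigma)) < tol
    mu <- mu_new
    sigma <- sigma_new
    if (done) break
  }
  a <- (bounds - mu) / sigma
  log_tail <- stats::pnorm(a, lower.tail = FALSE, log.p = TRUE)
  imputed <- mu + sigma * exp(stats::dnorm(a, log = TRUE) - log_tail)
  list(mu = mu, sigma = sigma, imputed = pmax(imputed, bounds), iterations = iter)
}

#' Singly impute nondetect delta-Ct values
#'
#' Treats nondetects as right-censored on the delta-Ct scale: a reaction that
#' never crossed threshold within `ct_ceiling` cycles implies
#' `dct > ct_ceiling - ref_ct` for that sample. Per gene (and, by default,
#' per diagnosis group) a normal model is fitted by EM to the detected values
#' and the censoring bounds; each nondetect is then replaced by the converged
#' conditional mean above its sample's bound, a deterministic single
#' imputation. Imputed values therefore always sit at or above the
#' sample-specific censoring bound; detected values are never touched.
#'
#' @param dct Long delta-Ct tibble from [compute_delta_ct()]; must carry
#'   `ref_ct` (or supply `lod_dct`).
#' @param meta Optional sample metadata holding the grouping variable.
#' @param group Name of the grouping column in `meta` (default
#'   `"diagnosis"`); set `pooled = TRUE` to ignore grouping.
#' @param ct_ceiling Instrument detection ceiling in cycles (default 40).
#' @param lod_dct Optional per-sample named vector of censoring bounds on the
#'   delta-Ct scale, overriding `ct_ceiling - ref_ct`.
#' @param pooled Fit one model per gene across all samples.
#' @param max_iter,tol EM control.
#' @return The completed tibble: same rows, `nondetect` all `FALSE`.
#' @export
impute_nondetects <- function(dct, meta = NULL, group = "diagnosis",
                              ct_ceiling = 40, lod_dct = NULL,
                              pooled = FALSE, max_iter = 200, tol = 1e-6) {
  stopifnot(max_iter >= 1, tol > 0)
  if (!any(dct$nondetect)) return(dct)

  if (is.null(lod_dct)) {
    if (!"ref_ct" %in% names(dct)) {
      stop("Need `ref_ct` column (or explicit `lod_dct`) to derive censoring bounds",
           call. = FALSE)
    }
    bound <- ct_ceiling - dct$ref_ct
  } else {
    bound <- unname(lod_dct[dct$sample_id])
    if (anyNA(bound)) stop("`lod_dct` missing for some samples", call. = FALSE)
  }

  n_det <- tapply(!dct$nondetect, dct$gene, sum)
  if (any(n_det < 2)) {
    stop("Gene(s) with fewer than 2 detected values: ",
         paste(names(n_det)[n_det < 2], collapse = ", "), call. = FALSE)
  }

  grp <- rep("all", nrow(dct))
  if (!pooled && !is.null(meta) && group %in% names(meta)) {
    grp <- as.character(meta[[group]][match(dct$sample_id, meta$sample_id)])
    grp[is.na(grp)] <- "all"
  }

  dct$.bound <- bound
  dct$.grp <- grp
  out <- dct
  for (g in unique(dct$gene[dct$nondetect])) {
    rows_g <- which(dct$gene == g)
    for (h in unique(dct$.grp[rows_g][dct$nondetect[rows_g]])) {
      rows <- rows_g[dct$.grp[rows_g] == h]
      det <- rows[!dct$nondetect[rows]]
      cen <- rows[dct$nondetect[rows]]
      if (length(det) < 2) {
        warning("Gene ", g, ", group ", h,
                ": fewer than 2 detected values; falling back to pooled estimate",
                call. = FALSE)
        det <- rows_g[!dct$nondetect[rows_g]]
      }
      fit <- censored_normal_em(dct$dct[det], dct$.bound[cen],
                                max_iter = max_iter, tol = tol)
      out$dct[cen] <- fit$imputed
    }
  }
  out$nondetect <- FALSE
  out$.bound <- NULL
  out$.grp <- NULL
  attr(out, "reference_gene") <- attr(dct, "reference_gene")
  out
}
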