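#' @importFrom rlang %||% .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# Median under right-censoring on the delta-Ct scale.
#
# Nondetects rank above every detected delta-Ct (they correspond to lower
# expression), which respects the within-sample ordinal scaling of delta-Ct
# when some genes are below the detection threshold. The median is taken
# over the censored ranking; whenever a required order statistic is itself a
# nondetect the median is undefined and NA is returned. For odd-sized gene
# sets this coincides with masking when more than half the genes are
# nondetect.
censored_median <- function(values, nondetect) {
  stopifnot(length(values) == length(nondetect))
  k <- length(values)
  if (k == 0L) return(NA_real_)
  det <- sort(values[!nondetect])
  d <- length(det)
  if (k %% 2L == 1L) {
    idx <- (k + 1L) %/% 2L
    if (idx <= d) det[idx] else NA_real_
  } else {
    lo <- k %/% 2L
    hi <- lo + 1L
    if (hi <= d) (det[lo] + det[hi]) / 2 else NA_real_
  }
}

# Long (sample_id, gene, value) -> samples x genes matrix.
dct_matrix <- function(dct, value = "dct", mask_nondetect = TRUE) {
  stopifnot(all(c("sample_id", "gene", value) %in% names(dct)))
  v <- dct[[value]]
  if (mask_nondetect && "nondetect" %in% names(dct)) v[dct$nondetect] <- NA_real_
  wide <- tidyr::pivot_wider(
    tibble::tibble(sample_id = dct$sample_id, gene = dct$gene, value = v),
    names_from = "gene", values_from = "value"
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample_id
  m
}

# samples x genes matrix -> long tibble
matrix_to_long <- function(m, value = "dct") {
  out <- tibble::tibble(
    sample_id = rep(rownames(m), times = ncol(m)),
    gene = rep(colnames(m), each = nrow(m)),
    value = as.vector(m)
  )
  names(out)[names(out) == "value"] <- value
  out
}

check_corr <- function(corr) {
  if (!is.matrix(corr) || nrow(corr) != ncol(corr)) {
    stop("`corr` must be a square correlation matrix", call. = FALSE)
  }
  if (max(abs(corr - t(corr))) > 1e-8) {
    stop("`corr` must be symmetric", call. = FALSE)
  }
  invisible(corr)
}
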