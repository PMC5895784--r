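#' Read a wide-format Ct table
#'
#' Reads a qPCR cycle-threshold CSV with one row per sample and one column
#' per gene; the first column holds sample identifiers. Nondetects (wells
#' that never crossed threshold) are encoded as empty cells or the literal
#' token `"Undetermined"`; both are accepted.
#'
#' @param path CSV file path (UTF-8, header row of gene ids).
#' @param undetermined Tokens treated as nondetects.
#' @return A long tibble with columns `sample_id`, `gene`, `ct` (NA where
#'   undetected) and `detected` (logical).
#' @export
read_ct_csv <- function(path, undetermined = c("", "Undetermined")) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2) stop("Ct table needs a sample column plus gene columns", call. = FALSE)
  names(raw)[1] <- "sample_id"
  if (anyDuplicated(raw$sample_id)) stop("Duplicate sample ids in Ct table", call. = FALSE)
  if (anyDuplicated(names(raw)[-1])) stop("Duplicate gene ids in Ct table", call. = FALSE)
  long <- tidyr::pivot_longer(raw, -"sample_id", names_to = "gene", values_to = "raw")
  detected <- !(is.na(long$raw) | long$raw %in% undetermined)
  ct <- suppressWarnings(as.numeric(long$raw))
  if (any(detected & !is.finite(ct))) {
    bad <- unique(long$sample_id[detected & !is.finite(ct)])
    stop("Non-numeric Ct values for sample(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ct[!detected] <- NA_real_
  tibble::tibble(sample_id = long$sample_id, gene = long$gene,
                 ct = ct, detected = detected)
}

#' Write a Ct table to CSV
#'
#' Inverse of [read_ct_csv()]: wide layout, nondetects written as
#' `"Undetermined"`.
#'
#' @param ct Long Ct tibble (`sample_id`, `gene`, `ct`, `detected`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ct_csv <- function(ct, path) {
  val <- ifelse(ct$detected, format_num(ct$ct), "Undetermined")
  wide <- tidyr::pivot_wider(
    tibble::tibble(sample_id = ct$sample_id, gene = ct$gene, value = val),
    names_from = "gene", values_from = "value")
  readr::write_csv(wide, path, progress = FALSE)
  invisible(path)
}

format_num <- function(x) formatC(x, digits = 12, format = "g")

#' Normalize Ct to delta-Ct against a reference gene
#'
#' Computes `dct[s, g] = ct[s, g] - ct[s, reference]` and carries nondetects
#' forward as an explicit mask (`nondetect = !detected`). The reference gene
#' must be detected in every sample; its column is removed from the output.
#' The per-sample reference Ct is retained (`ref_ct`) because the detection
#' ceiling on the delta-Ct scale is `ct_ceiling - ref_ct`.
#'
#' @param ct Long Ct tibble from [read_ct_csv()].
#' @param reference_gene Reference (housekeeping) gene id, default `"PPIA"`.
#' @return Long tibble `sample_id`, `gene`, `dct`, `nondetect`, `ref_ct`
#'   with attribute `reference_gene`. Lower `dct` means higher expression.
#' @examples
#' ct <- tibble::tibble(
#'   sample_id = "s1", gene = c("ISG15", "PPIA"),
#'   ct = c(25, 20), detected = TRUE
#' )
#' compute_delta_ct(ct, "PPIA")$dct # 5
#' @export
compute_delta_ct <- function(ct, reference_gene = "PPIA") {
  stopifnot(all(c("sample_id", "gene", "ct", "detected") %in% names(ct)))
  ref <- ct[ct$gene == reference_gene, ]
  if (nrow(ref) == 0) {
    stop("Reference gene ", reference_gene, " not present in Ct table", call. = FALSE)
  }
  samples <- unique(ct$sample_id)
  missing_ref <- setdiff(samples, ref$sample_id[ref$detected])
  if (length(missing_ref) > 0) {
    stop("Reference gene ", reference_gene, " undetected in sample(s): ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  }
  out <- ct[ct$gene != reference_gene, ]
  ref_ct <- ref$ct[match(out$sample_id, ref$sample_id)]
  out <- tibble::tibble(
    sample_id = out$sample_id,
    gene = out$gene,
    dct = ifelse(out$detected, out$ct - ref_ct, NA_real_),
    nondetect = !out$detected,
    ref_ct = ref_ct
  )
  attr(out, "reference_gene") <- reference_gene
  out
}

#' Expression-scale transform of delta-Ct
#'
#' `2^(-dct)`: relative expression with respect to the reference gene.
#' Strictly decreasing in delta-Ct.
#'
#' @param dct_value Numeric vector of delta-Ct values (cycles).
#' @return Dimensionless relative expression.
#' @examples
#' fold_expression(c(0, 1, -2)) # 1, 0.5, 4
#' @export
fold_expression <- function(dct_value) 2^(-dct_value)

#' Reflect delta-Ct values
#'
#' Negates delta-Ct so that larger values mean higher expression, the scale
#' on which mixture histograms are drawn. The reflection is a plain sign
#' flip: it preserves all orderings and mixture shapes, and any affine
#' reflection yields the same downstream classification. For data frames the
#' `dct` column is negated and the nondetect mask kept as-is.
#'
#' @param dct Numeric vector, or a long delta-Ct tibble with a `dct` column.
#' @return Same shape as the input, with delta-Ct negated.
#' @export
reflect_dct <- function(dct) {
  if (is.data.frame(dct)) {
    stopifnot("dct" %in% names(dct))
    dct$dct <- -dct$dct
    dct
  } else {
    -dct
  }
}

#' Read / write delta-Ct tables
#'
#' Wide CSV, first column sample id, one column per gene, nondetects as
#' `"Undetermined"`. A `ref_ct` column (per-sample reference Ct) is written
#' when present and recognized on reading.
#'
#' @param path CSV path.
#' @param reference_gene Reference gene recorded on the returned tibble.
#' @return `read_dct_csv()` returns a long delta-Ct tibble as from
#'   [compute_delta_ct()].
#' @export
read_dct_csv <- function(path, reference_gene = "PPIA") {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  names(raw)[1] <- "sample_id"
  ref_ct <- NULL
  if ("ref_ct" %in% names(raw)) {
    ref_ct <- as.numeric(raw$ref_ct)
    raw$ref_ct <- NULL
  }
  long <- tidyr::pivot_longer(raw, -"sample_id", names_to = "gene", values_to = "raw")
  nondetect <- is.na(long$raw) | long$raw %in% c("", "Undetermined")
  out <- tibble::tibble(
    sample_id = long$sample_id, gene = long$gene,
    dct = ifelse(nondetect, NA_real_, suppressWarnings(as.numeric(long$raw))),
    nondetect = nondetect
  )
  if (!is.null(ref_ct)) {
    out$ref_ct <- ref_ct[match(out$sample_id, raw$sample_id)]
  }
  attr(out, "reference_gene") <- reference_gene
  out
}

#' @param dct Long delta-Ct tibble to write.
#' @rdname read_dct_csv
#' @export
write_dct_csv <- function(dct, path) {
  val <- ifelse(dct$nondetect, "Undetermined", format_num(dct$dct))
  wide <- tidyr::pivot_wider(
    tibble::tibble(sample_id = dct$sample_id, gene = dct$gene, value = val),
    names_from = "gene", values_from = "value")
  if ("ref_ct" %in% names(dct)) {
    refs <- dct[!duplicated(dct$sample_id), c("sample_id", "ref_ct")]
    wide$ref_ct <- format_num(refs$ref_ct[match(wide$sample_id, refs$sample_id)])
  }
  readr::write_csv(wide, path, progress = FALSE)
  invisible(path)
}
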