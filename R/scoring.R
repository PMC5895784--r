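#' Compute IFN Score A and IFN Score B
#'
#' Applies a two-score gene panel (by default the packaged published panel)
#' to a delta-Ct table. Each score is the median delta-Ct over its 13-gene
#' set, with nondetects ranked above all detected values, then transformed
#' to the expression scale as `2^(-score)`. A score is masked (NA) when its
#' median order statistic is censored, or when more genes are absent from
#' the data than `max_missing` allows.
#'
#' @param dct Long delta-Ct tibble (`sample_id`, `gene`, `dct`,
#'   `nondetect`).
#' @param panel Panel tibble from [ifn_panel()] or [read_panel_yaml()];
#'   rows with `score` `"A"`/`"B"` define the two gene sets.
#' @param max_missing Number of panel genes per score allowed to be absent
#'   from `dct` (default 0: every gene must be present).
#' @return Tibble `sample_id`, `score_a_dct`, `score_b_dct`, `score_a_expr`,
#'   `score_b_expr`, `panel_version`.
#' @examples
#' dct <- tidyr::expand_grid(sample_id = "s1", gene = ifn_panel()$gene)
#' dct$dct <- 5
#' dct$nondetect <- FALSE
#' compute_ifn_scores(dct) # both scores 5, expression 2^-5
#' @export
compute_ifn_scores <- function(dct, panel = ifn_panel(), max_missing = 0) {
  sets <- panel_gene_sets(panel)
  if (length(intersect(sets$A, sets$B)) > 0) {
    stop("Score A and Score B gene sets overlap", call. = FALSE)
  }
  if (length(sets$A) == 0 || length(sets$B) == 0) {
    stop("Panel must define non-empty Score A and Score B gene sets", call. = FALSE)
  }
  genes_present <- unique(dct$gene)
  unknown <- setdiff(genes_present, c(panel$gene, genes_present))
  miss_a <- setdiff(sets$A, genes_present)
  miss_b <- setdiff(sets$B, genes_present)
  if (length(miss_a) > max_missing && length(miss_b) > max_missing) {
    stop("Too many panel genes absent from data (A: ",
         paste(miss_a, collapse = ", "), "; B: ",
         paste(miss_b, collapse = ", "), ")", call. = FALSE)
  }

  score_one <- function(genes, missing) {
    if (length(missing) > max_missing) {
      return(rep(NA_real_, length(unique(dct$sample_id))))
    }
    s <- median_factor_scores(dct, list(score = setdiff(genes, missing)))
    s$score
  }
  samples <- unique(dct$sample_id)
  out <- tibble::tibble(
    sample_id = samples,
    score_a_dct = score_one(sets$A, miss_a),
    score_b_dct = score_one(sets$B, miss_b)
  )
  out$score_a_expr <- fold_expression(out$score_a_dct)
  out$score_b_expr <- fold_expression(out$score_b_dct)
  out$panel_version <- attr(panel, "panel_version") %||% "custom"
  out
}

#' Read / write score tables
#'
#' CSV with columns `sample_id`, `score_a_dct`, `score_b_dct`,
#' `score_a_expr`, `score_b_expr` (and `panel_version`).
#'
#' @param scores Score tibble from [compute_ifn_scores()].
#' @param path CSV path.
#' @return `read_scores_csv()` returns the score tibble.
#' @export
write_scores_csv <- function(scores, path) {
  readr::write_csv(scores, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_scores_csv
#' @export
read_scores_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    panel_version = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
}

#' Score distributions by group
#'
#' Boxplots of both scores on the expression scale, split by a metadata
#' group (typically diagnosis), on a log scale.
#'
#' @param scores Score tibble.
#' @param meta Metadata with `sample_id` and the grouping column.
#' @param group Grouping column name (default `"diagnosis"`).
#' @return A ggplot object.
#' @export
plot_scores <- function(scores, meta, group = "diagnosis") {
  d <- dplyr::inner_join(scores, meta[, c("sample_id", group)], by = "sample_id")
  d <- tidyr::pivot_longer(d, c("score_a_expr", "score_b_expr"),
                           names_to = "score", values_to = "expression")
  d$score <- ifelse(d$score == "score_a_expr", "IFN Score A", "IFN Score B")
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[group]], y = .data$expression,
                                  fill = .data[[group]])) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~score) +
    ggplot2::labs(x = NULL, y = expression(2^{-Delta*Ct})) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
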