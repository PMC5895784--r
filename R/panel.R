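#' Packaged ISG panel with published factor loadings
#'
#' Returns the 31-gene TaqMan interferon-stimulated-gene (ISG) panel used to
#' derive the two-score system, together with its module annotations and the
#' published rotated (promax) pattern loadings. Thirteen genes form IFN Score
#' A, thirteen form IFN Score B, four were excluded as cross-loaded and one
#' (CASP1) loaded on neither factor.
#'
#' Loadings not reported (below the 0.4 display threshold) are stored as 0;
#' CXCL10 carries its parenthesized negative loading on the second factor.
#' Module labels (`M1.2`, `M3.4`, `M5.12`, `extra`) are annotation metadata
#' only and play no role in any computation.
#'
#' @param version Panel version string; currently only `"table1-v1"`.
#' @return A tibble with columns `gene`, `module`, `score` (`"A"`, `"B"`,
#'   `"cross"`, or `"none"`), `loading_a`, `loading_b`, and attribute
#'   `panel_version`.
#' @examples
#' panel <- ifn_panel()
#' table(panel$score)
#' @export
ifn_panel <- function(version = "table1-v1") {
  if (!identical(version, "table1-v1")) {
    stop("Unknown panel version: ", version, call. = FALSE)
  }
  a <- tibble::tribble(
    ~gene, ~module, ~loading_a,
    "ISG15",   "M1.2", 0.96,
    "IFI44",   "M1.2", 0.80,
    "IFI27",   "extra", 0.77,
    "CXCL10",  "M3.4", 0.71,
    "RSAD2",   "M1.2", 0.70,
    "IFIT1",   "M1.2", 0.67,
    "IFI44L",  "M1.2", 0.66,
    "CCL8",    "M3.4", 0.58,
    "XAF1",    "M1.2", 0.54,
    "GBP1",    "M3.4", 0.46,
    "IRF7",    "M3.4", 0.46,
    "CEACAM1", "M3.4", 0.45,
    "LAMP3",   "M3.4", 0.40
  )
  a$score <- "A"
  a$loading_b <- ifelse(a$gene == "CXCL10", -0.41, 0)

  b <- tibble::tribble(
    ~gene, ~module, ~loading_b,
    "IFIH1",    "M3.4",  0.45,
    "PHF11",    "M3.4",  0.58,
    "SERPING1", "M3.4",  0.60,
    "IFI16",    "M3.4",  0.64,
    "BST2",     "M5.12", 0.74,
    "SP100",    "M5.12", 0.74,
    "NT5C3B",   "M5.12", 0.80,
    "SOCS1",    "M5.12", 0.84,
    "TRIM38",   "M5.12", 0.87,
    "UNC93B1",  "M5.12", 0.88,
    "UBE2L6",   "M5.12", 0.89,
    "STAT1",    "M5.12", 0.94,
    "TAP1",     "M5.12", 0.98
  )
  b$score <- "B"
  b$loading_a <- 0

  x <- tibble::tribble(
    ~gene, ~module, ~loading_a, ~loading_b,
    "IFI6",    "extra", 0.51, 0.45,
    "HERC5",   "M1.2",  0.43, 0.59,
    "EIF2AK2", "M1.2",  0.42, 0.64,
    "MX1",     "M1.2",  0.40, 0.56
  )
  x$score <- "cross"

  casp1 <- tibble::tibble(gene = "CASP1", module = "M5.12",
                          loading_a = 0, loading_b = 0, score = "none")

  panel <- dplyr::bind_rows(a, b, x, casp1)
  panel <- panel[, c("gene", "module", "score", "loading_a", "loading_b")]
  attr(panel, "panel_version") <- version
  panel
}

#' Gene sets of a panel
#'
#' @param panel A panel tibble as returned by [ifn_panel()].
#' @return Named list of character vectors: `A`, `B` (scored genes),
#'   `cross` (cross-loaded, excluded), `none` (unassigned).
#' @export
panel_gene_sets <- function(panel = ifn_panel()) {
  split(panel$gene, factor(panel$score, levels = c("A", "B", "cross", "none")))
}

#' Read / write gene panels as YAML
#'
#' A panel file stores the panel name, ordered gene list, module map and
#' (optionally) published loadings, so user-derived panels from
#' [derive_factor_solution()] travel through the same interface as the
#' packaged one.
#'
#' @param path File path.
#' @return `read_panel_yaml()` returns a panel tibble;
#'   `write_panel_yaml()` returns `path` invisibly.
#' @export
read_panel_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  genes <- vapply(y$genes, function(g) g$gene, character(1))
  if (anyDuplicated(genes)) stop("Duplicate genes in panel file", call. = FALSE)
  panel <- tibble::tibble(
    gene = genes,
    module = vapply(y$genes, function(g) g$module %||% "extra", character(1)),
    score = vapply(y$genes, function(g) g$score %||% "none", character(1)),
    loading_a = vapply(y$genes, function(g) as.numeric(g$loading_a %||% 0), numeric(1)),
    loading_b = vapply(y$genes, function(g) as.numeric(g$loading_b %||% 0), numeric(1))
  )
  attr(panel, "panel_version") <- y$name %||% "unnamed"
  panel
}

#' @param panel Panel tibble to write.
#' @rdname read_panel_yaml
#' @export
write_panel_yaml <- function(panel, path) {
  y <- list(
    name = attr(panel, "panel_version") %||% "unnamed",
    genes = lapply(seq_len(nrow(panel)), function(i) {
      list(gene = panel$gene[i], module = panel$module[i],
           score = panel$score[i],
           loading_a = panel$loading_a[i], loading_b = panel$loading_b[i])
    })
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
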