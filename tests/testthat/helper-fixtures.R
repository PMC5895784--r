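# Shared fixtures, built in code at test time.

# Long Ct tibble from a samples x genes matrix (NA = nondetect); a PPIA
# reference column with the given Ct is appended.
make_ct <- function(m, ref_ct = 20) {
  stopifnot(!is.null(colnames(m)))
  if (is.null(rownames(m))) rownames(m) <- paste0("s", seq_len(nrow(m)))
  ct <- tibble::tibble(
    sample_id = rep(rownames(m), times = ncol(m)),
    gene = rep(colnames(m), each = nrow(m)),
    ct = as.vector(m),
    detected = !is.na(as.vector(m))
  )
  dplyr::bind_rows(ct, tibble::tibble(sample_id = rownames(m), gene = "PPIA",
                                      ct = ref_ct, detected = TRUE))
}

# Long delta-Ct tibble from a samples x genes matrix (NA = nondetect).
make_dct <- function(m, ref_ct = 20) {
  if (is.null(rownames(m))) rownames(m) <- paste0("s", seq_len(nrow(m)))
  tibble::tibble(
    sample_id = rep(rownames(m), times = ncol(m)),
    gene = rep(colnames(m), each = nrow(m)),
    dct = as.vector(m),
    nondetect = is.na(as.vector(m)),
    ref_ct = ref_ct
  )
}

# Published pattern loadings as a 31 x 2 matrix (unreported entries 0).
panel_loading_matrix <- function(panel = ifn_panel()) {
  L <- cbind(panel$loading_a, panel$loading_b)
  rownames(L) <- panel$gene
  colnames(L) <- c("A", "B")
  L
}

# Zero-shift single-group cohort config: data drawn purely from the oblique
# two-factor loading model, used for structure-recovery tests.
loading_model_config <- function(n = 328, seed = 1, ...) {
  cohort_config(seed = seed, group_sizes = c(ALL = n),
                group_factor_shifts = list(ALL = c(0, 0)),
                age = list(ALL = c(45, 15)), ...)
}

# Align a 2-column pattern so ISG15 anchors column 1 and dominant signs are
# positive (mirrors the convention inside derive_factor_solution).
align_pattern <- function(P, phi = NULL) {
  if (abs(P["ISG15", 2]) > abs(P["ISG15", 1])) {
    P <- P[, 2:1]
    if (!is.null(phi)) phi <- phi[2:1, 2:1]
  }
  for (j in 1:2) {
    if (P[which.max(abs(P[, j])), j] < 0) {
      P[, j] <- -P[, j]
      if (!is.null(phi)) {
        phi[j, ] <- -phi[j, ]
        phi[, j] <- -phi[, j]
      }
    }
  }
  colnames(P) <- c("A", "B")
  if (is.null(phi)) P else list(pattern = P, phi = phi)
}

expect_no_na <- function(x) expect_false(anyNA(x))

# Samples x genes delta-Ct matrix straight from a generated Ct table.
dct_wide_for_test <- function(ct) {
  d <- compute_delta_ct(ct, "PPIA")
  ifnscore:::dct_matrix(d)
}
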