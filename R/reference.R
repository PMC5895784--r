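#' Published validation estimates shipped as reference data
#'
#' Age-adjusted expression ratios (with 90% confidence intervals) between
#' diagnostic groups for both IFN scores, and the mixture-classification
#' summaries, as published for the 328-sample validation cohort. These are
#' packaged so that simulation studies can set their generating values from
#' the published estimates without any external input.
#'
#' @return `ifn_reference_contrasts()`: tibble `contrast`, `score`,
#'   `ratio`, `ci_low`, `ci_high`.
#' @export
ifn_reference_contrasts <- function() {
  tibble::tribble(
    ~contrast,   ~score, ~ratio, ~ci_low, ~ci_high,
    "SLE vs HC", "A",      9.35,    5.50,    15.90,
    "SLE vs HC", "B",      3.90,    2.76,     5.52,
    "SLE vs RA", "A",      6.11,    3.42,    10.89,
    "SLE vs RA", "B",      1.26,    0.87,     1.85,
    "RA vs HC",  "A",      1.53,    0.75,     3.14,
    "RA vs HC",  "B",      3.09,    1.93,     4.94
  )
}

#' @return `ifn_reference_bimodality()`: tibble `classifier`,
#'   `proportion_high`, `mean_membership`.
#' @rdname ifn_reference_contrasts
#' @export
ifn_reference_bimodality <- function() {
  tibble::tribble(
    ~classifier,     ~proportion_high, ~mean_membership,
    "score_a",       0.45,             0.89,
    "IFI27",         0.46,             0.92,
    "score_b",       0.20,             0.97,
    "SP100",         0.32,             0.99
  )
}

#' @return `ifn_reference_cohort()`: tibble `diagnosis`, `n`, `age_mean`,
#'   `age_sd` for the validation cohort.
#' @rdname ifn_reference_contrasts
#' @export
ifn_reference_cohort <- function() {
  tibble::tribble(
    ~diagnosis, ~n,  ~age_mean, ~age_sd,
    "HC",        49L, 31.7,      8.8,
    "SLE",      114L, 45.7,     14.5,
    "UCTD",     133L, 47.7,     15.1,
    "RA",        32L, 52.2,     15.5
  )
}

#' @return `ifn_reference_phi()`: the published inter-factor correlation of
#'   the rotated two-factor solution.
#' @rdname ifn_reference_contrasts
#' @export
ifn_reference_phi <- function() 0.56
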