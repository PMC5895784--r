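# Default synthetic-cohort configuration.
#
# Group sizes and age distributions follow the published validation cohort;
# the latent two-factor structure uses the packaged panel loadings with the
# published inter-factor correlation. Group shifts of the latent factors are
# chosen so that the median-score contrast geometry matches the published
# age-adjusted expression ratios (Score A elevated in SLE only; Score B
# elevated in SLE and RA): a latent shift delta moves each gene's delta-Ct
# by -loading*delta, so the median score moves by about -median(loading)*delta
# (median Score A loading 0.66, Score B 0.80), and delta is set to
# log2(ratio)/median(loading). Clinical covariates are simple parametric
# stand-ins with configured links to the latent factors; they are not
# estimated from any real cohort.
group_sizes:
  HC: 49
  SLE: 114
  UCTD: 133
  RA: 32
factor_correlation: 0.56
# per-group mean shift of latent factors [A, B]; positive = higher expression
group_factor_shifts:
  HC: [0.0, 0.0]
  SLE: [4.89, 2.45]
  UCTD: [2.20, 1.60]
  RA: [0.93, 2.03]
age:
  HC: [31.7, 8.8]
  SLE: [45.7, 14.5]
  UCTD: [47.7, 15.1]
  RA: [52.2, 15.5]
gene_baseline: 6.0     # HC mean delta-Ct per gene, cycles
ct_ceiling: 40.0       # instrument detection limit, cycles
ref_ct_mean: 20.0      # reference-gene Ct
ref_ct_sd: 0.3
# clinical covariate links (latent factors are standardized within group)
ana_count_base: 0.25   # log-scale Poisson intercept for patients
ana_count_slope: 0.45  # per unit latent factor A
lymphocyte_log_mean: 0.55
lymphocyte_log_sd: 0.35
lymphocyte_slope: -0.18
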