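# resilvar

Quantitative-genetic analysis of growth resilience from longitudinal fish
weights.

Fish that keep growing steadily through environmental perturbations are,
by a useful operational definition, more resilient than fish whose growth
fluctuates.  `resilvar` implements a complete pipeline for turning repeated
body-weight records into a heritable resilience indicator and estimating
its genetics with a genomic animal model.  It is aimed at aquaculture
breeding analysts working with grow-out experiments in contrasting
environments (e.g. an aerated and a non-aerated pond).

## The method in brief

1. **Growth model.**  Weights follow `W_it = a + b_i * t^f` with one
   overall weight exponent `f`, estimated by profiled nonlinear least
   squares (`estimate_weight_exponent()`).
2. **Linearisation.**  Raising weights to `1/f` makes growth linear in
   age; the per-fish OLS slope of `W^(1/f)` on age is the daily growth
   coefficient `DGC` (g^(1/f)/day), and its fitted line gives expected
   weights (`fit_growth_lines()`).  On this scale the deviation spread is
   approximately constant over ages, unlike the gram or cube-root scales
   (`heteroscedasticity_profile()`).
3. **Indicators.**  `LnVar_ind` = ln of the variance of a fish's
   deviations from its own line; `LnVar_coh` = the cohort analogue using
   standardised deviations from the hapa x sex x pond cohort mean
   (`resilience_table()`).
4. **Genomic relationships.**  VanRaden method-2 GRM from SNP dosages
   with MAF filtering, mean imputation and identity blending
   (`compute_grm()`).
5. **Genetics.**  AI-REML animal models — univariate, within-pond
   bivariate, and cross-environment bivariate with the residual covariance
   fixed at zero — return variance components, heritabilities
   `h2 = sigma2_A / sigma2_P`, genetic/phenotypic correlations with
   delta-method SEs, and BLUP breeding values
   (`reml_univariate()`, `reml_bivariate()`, `predict_ebv()`).
6. **Synthetic data.**  A generator emulating a two-pond grow-out with
   72 sires x 200 dams, genomic breeding values on the growth slope and on
   the log deviation variance, and genotype-by-environment correlation
   structure (`sim_config()`, `simulate_genotypes()`,
   `simulate_weights()`), so the whole chain is testable without
   confidential field data.

## Worked example

```r
library(resilvar)

cfg <- sim_config(n_fish_per_pond = 150, n_sires = 24, n_dams = 48,
                  n_snps = 1500, seed = 42)
geno <- simulate_genotypes(cfg)
sim  <- simulate_weights(cfg, geno)

efit <- estimate_weight_exponent(sim$records)
efit
#> Allometric growth fit  W = a + b_i * t^f
#>   f = 1.7582   a = 0.3657   SSE = 1304
#>   300 fish, 1500 observations

lines <- fit_growth_lines(sim$records, efit$f)
rt <- resilience_table(sim$records, lines, cohort_floor = 4)
grm <- compute_grm(geno)

d <- build_design(rt[rt$pond == "non_aerated", ], "lnvar_ind", grm = grm)
fit <- reml_univariate(d$y, d$X, d$ids, grm)
fit
#> Genomic animal model (univariate), REML
#>   traits: trait1   n = 150   logLik = -104.3213
#>  component estimate     se
#>        A11   0.4153 0.2759
#>        E11   0.9923 0.2497
#>   h2(trait1) = 0.295 (se 0.182)
```

The generating heritability of the log deviation variance in the
non-aerated pond is 0.28 (additive variance 0.44 against a phenotypic
variance of about 1.56); the estimate of 0.295 lands nearby, though at 150
fish it is noisy (se 0.18) — at the experiment's scale of ~800 fish per
pond the estimator recovers it to within a few points (see the acceptance
script below).  The estimated exponent 1.758 sits close to the generating
1.77, and mean `DGC` of 0.167 (aerated) and 0.133 (non-aerated)
g^(1/f)/day reproduces the configured growth difference between ponds.

`run_full_analysis()` chains all stages and writes the report bundle
(descriptive tables, component tables, correlation matrices,
cross-environment estimates, deviation diagnostics, EBV scatter, JSON run
record) into an output directory;
`Rscript inst/cli/resilvar.R report --seed 1 --out out/` does the same
from a shell.

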