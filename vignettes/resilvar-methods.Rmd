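---
title: "Growth resilience from log-variance of weight deviations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth resilience from log-variance of weight deviations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Fish that grow steadily are presumed to cope better with environmental
perturbation than fish whose growth fluctuates, even when the perturbations
themselves are unobserved.  A practical indicator of this "resilience" is
the variance of an individual's deviations from its own expected growth
trajectory, log-transformed to tame its skew: **LnVar**.  `resilvar`
implements the full analysis chain for longitudinal body weights from a
two-pond (aerated vs. non-aerated) tilapia-style grow-out: growth-curve
fitting, indicator construction, genomic relationship matrices, and
REML variance-component estimation with an animal model, plus a synthetic
data generator that makes every stage testable without confidential field
data.

# Growth model and indicator

Observed weights follow the allometric form

$$W_{it} = a + b_i\,t^{f},$$

with a shared intercept $a$, per-fish slope $b_i$ and one overall weight
exponent $f$.  `estimate_weight_exponent()` minimises the pooled residual
sum of squares over $(a, f, \{b_i\})$.  For fixed $f$ the model is linear
in all remaining parameters, so they are profiled in closed form and the
outer problem is a bounded one-dimensional optimisation in $f$, preceded by
a coarse grid that doubles as a unimodality diagnostic.  This profiled
formulation is exact — it is the same objective a joint nonlinear solver
would minimise — but cannot be trapped by poor starting values for the
per-fish slopes.

Raising weights to $1/f$ linearises growth: `fit_individual_line()`
regresses $W^{1/f}$ on age per fish.  The slope is the daily growth
coefficient (DGC, g$^{1/f}$/day), the fitted line gives the expected
weights, and the residuals are the deviations.  Because each fish's
regression carries its own intercept, the deviations sum to zero per fish
by construction — a property the test suite checks at machine precision.
**LnVar_ind** is the natural log of the sample variance (denominator
$n-1$) of these deviations.  The $n-1$ denominator is a convention; with a
fixed number of measurement ages any other denominator shifts LnVar by a
constant that is absorbed by the model mean, so no genetic parameter
changes.

Deviations can be computed on three scales (`compute_deviations()`): the
$1/f$ scale, the observed gram scale, and the conventional cube-root
scale.  On the gram scale the deviation spread grows strongly with fish
size; on the $1/f$ scale it is approximately flat.
`heteroscedasticity_profile()` quantifies this as the ratio
$\max_t \mathrm{SD}_t / \min_t \mathrm{SD}_t$.  `compare_linear_quadratic()`
checks the straight-line assumption on the $1/f$ scale by testing a
quadratic age term with per-fish intercepts.

**LnVar_coh** replaces the individual expected weight with the cohort mean
(cohort = nursery hapa x sex x pond).  The deviations are standardised by
the cohort SD at each age before taking the per-fish variance and log.
Standardisation is a documented assumption, not a quotation of any fixed
reference: with raw gram deviations the indicator's location would be
dominated by the harvest-age spread, while standardised deviations put all
ages on a common footing and produce the non-positive typical values seen
in cohort-based indicators.  A raw-deviation mode is available behind the
`standardize` flag.  Cohort-age cells below `cohort_floor` (default 5)
fish yield missing values rather than unstable standardisations.
Degenerate zero-variance fish yield missing values, not `-Inf`, so mixed
models downstream remain well posed.

# Genomic relationships

`compute_grm()` implements the marker-wise standardisation form of the
genomic relationship matrix (VanRaden's method 2):

$$G_{ij} = \frac{1}{m}\sum_k
\frac{(x_{ik}-2p_k)(x_{jk}-2p_k)}{2p_k(1-p_k)},$$

with allele frequencies estimated in-sample, MAF filtering (default 0.01),
per-SNP mean imputation of missing dosages, and identity blending
$(1-\beta)G + \beta I$ with $\beta = 0.01$, which guarantees the positive
definiteness REML requires.  With in-sample frequencies the rows of $G$
sum to zero, so the mean off-diagonal equals $-\bar g_{ii}/(n-1)$ — a
property used as a test.

# The animal model and AI-REML

The phenotype model is

$$y_{ijk} = \mu + \mathrm{CAGE}_i + \mathrm{SEX}_j + b\,\mathrm{SW}_k
          + a_k + e_{ijk},$$

with nursery cage (hapa) and sex as fixed effects, the start-weight
covariate for harvest weight only, one additive genetic effect per fish
with covariance $\sigma^2_A G$, and i.i.d. residuals.  Bivariate fits use
$a \sim N(0,\,G \otimes C)$ and $e \sim N(0,\,I \otimes R)$ with 2x2
genetic and residual covariance matrices; for the cross-environment design
each fish performs in one pond only, so the residual covariance is
structurally zero and is constrained, while the genetic covariance is
identified through relatives split across ponds.

`reml_univariate()` / `reml_bivariate()` maximise the REML log-likelihood
with the average-information (AI) algorithm.  Since
$V = \sum_k \theta_k Q_k$ is linear in the components, the score and AI
matrix have the standard closed forms.  Numerical choices, all exercised
by tests:

* **Parameterisation.**  Variances on the log scale and correlations on
  the atanh scale, so the working space is unconstrained and estimates
  respect $\sigma^2 \ge 0$, $|r| \le 1$ by construction.  The correlation
  cap corresponds to $|r| \le 0.99999$.
* **Safeguards.**  Levenberg-Marquardt ridge escalation when the plain AI
  step is not an ascent, step halving, and a scaled-gradient fallback;
  every accepted iteration is non-decreasing in log-likelihood (tested).
* **Boundaries.**  Parameters pinned at a cap with an outward gradient are
  frozen (active set), so $\hat\sigma^2_A \to 0$ and $|\hat r_g| \to 1$
  solutions converge cleanly and are flagged `boundary`.  When a genetic
  correlation lands on $|r|=1$ from the default start, the fit is repeated
  once from a moderate interior start and the higher-likelihood solution
  kept.
* **Convergence.**  Relative log-likelihood change below `1e-8` together
  with either a parameter change below `1e-6` or a vanishing Newton
  decrement (the ascent still promised by the current step); maximum 200
  iterations.  On small instances the optimum agrees with a
  derivative-free maximisation of the same constrained likelihood to
  better than `1e-3` in every component (tested against an independent
  implementation of the likelihood).
* **Uncertainty.**  Component SEs from the inverse AI matrix at the
  optimum; SEs of $h^2$, $r_g$ and $r_p$ by the delta method.  SEs are
  suppressed at boundary solutions.
* **EBVs.**  BLUP solutions $\hat a = \mathrm{Cov}(a,y)\,P\,y$ for every
  fish in the GRM — including, for cross-environment fits, the pond in
  which a fish was never recorded, predicted through the genetic
  covariance — with reliabilities from the prediction error variance.

The same-fish bivariate fit and the cross-environment fit share one
engine; the residual covariance structure is the only difference.  Fits are
invariant to fish ordering and to the fixed-effect coding (tested).

# The synthetic data generator

The generator inverts the indicator's definition so that the heritable
signal sits exactly where the analysis looks for it.  For fish $i$ at age
$t$ (days 1, 55, 104, 167, 217 by default):

$$W_{it}^{1/f} = a_i + b_i t + e_{it}, \qquad
  e_{it} \sim N\!\big(0,\, e^{\eta_i}\big),$$

where $a_i$ is the linearised intercept plus hapa and sex shifts, the
slope $b_i$ carries a genomic breeding value and environmental noise, and
the per-fish log deviation variance $\eta_i$ carries its own breeding
value and noise.  Breeding values are genomic: every SNP carries a
4-variate effect — (slope, log-variance) x (aerated, non-aerated) — drawn
with a configurable correlation matrix, so the realised BV covariance
matches the VanRaden GRM computed from the same genotypes.  Genotypes come
from 72 sires x 200 dams (dams nested in sires) by Mendelian gene
dropping; fish are assigned to ponds in halves so each full-sib family
spans both ponds, which is what identifies cross-environment genetic
correlations.

Default generating values and where they come from:

* exponent $f = 1.77$; mean DGC 0.16 / 0.13 g$^{1/f}$/day (aerated /
  non-aerated),
* slope variances: additive 0.25e-3 / 0.12e-3, environmental chosen so
  the phenotypic DGC variances are 0.88e-3 / 0.48e-3,
* log-variance additive variances 0.060 / 0.440, environmental spread
  0.062 / 0.188 chosen so that the LnVar_ind phenotypic variances reach
  1.057 / 1.563 after adding the sampling noise of a log variance on 3
  degrees of freedom ($\psi'(3/2) = 0.935$).  With these values the full
  pipeline reproduces heritabilities of about 0.06 (aerated) and 0.28
  (non-aerated) for LnVar_ind as emergent quantities,
* cross-pond genetic correlation 0.50 for the log-variance trait; the
  cross-pond slope correlation is not reported for the source experiment
  and defaults to 0.80, a typical value for a growth trait under moderate
  genotype-by-environment interaction; cross-trait cross-pond entries are
  -0.35, keeping the 4x4 matrix positive definite.

**The intercept compromise.**  The generating model is exactly linear on
the $1/f$ scale, while the exponent estimator fits the observed-scale
model with a shared intercept.  These two descriptions coincide only when
the linearised intercept is near zero (pure allometric growth from
near-zero size); with a realistic tilapia stocking weight (about 40 g,
linearised intercept around 8) the observed-scale fit systematically
returns an exponent near 1.46 for a generating exponent of 1.77.  The
default intercept is therefore small (0.2 g$^{1/f}$), keeping the
recovered exponent within about 0.01-0.02 of the generating value.  The
consequences are that simulated start and harvest weights are smaller
than a real grow-out's and the location of LnVar_ind is shifted downward
(the baseline log deviation variance defaults to -5.7); every
variance-component structure — heritabilities, genetic correlations, the
heteroscedasticity contrast between scales — is unaffected, and those
structures are what the package's validation targets.  Real data are not
subject to this compromise: the exponent is re-estimated from the data at
hand.

Positivity of weights is enforced by redrawing offending deviations (at
most 100 times per observation; the redraw count is recorded in the truth
object and pathological configurations raise an error naming the fish and
age).  Missing harvest records are missing-at-random drops.  Unknown sex
is an independent 5% fraction by default.

What the generator does **not** emulate: dissolved-oxygen dynamics,
feeding, mortality and tagging loss, mass-spawning family imbalance
(available as an option, off by default), genotyping error and
missingness, and selection history.  Passing recovery tests on these
simulations therefore demonstrates the correctness and calibration of the
estimation machinery under the stated generative model, not field validity
of the indicator.

# Validation scale and Monte Carlo design

Recovery checks run at the scale of the motivating experiment where that
matters (about 800 fish per pond for heritability and cross-environment
correlation recovery, 5 ages per fish) and at reduced sizes where only the
algebra is under test.  Genotypes are simulated at 2,000 SNPs for the
recovery studies: with 272 founders, marker sampling noise in the GRM is
already far below the phenotypic sampling noise that dominates these
experiments, and the full 11,293-SNP panel is exercised separately for
scale.  Replicate counts (10-20) balance the Monte Carlo standard error of
a mean against runtime; the test suite uses somewhat smaller designs than
the acceptance script where a tolerance is still comfortably resolvable.

Two estimator properties at the study's own parameter values deserve
notice, established with the package's simulations:

* **Within-pond genetic correlations** of strongly heritable trait pairs
  recover their generating values with mild attenuation toward zero
  (roughly 0.05-0.08 at $|r_g| = 0.68$, n = 800), the familiar skew of
  correlation estimators near the edge of their range.
* **The cross-environment genetic correlation at a near-zero heritability
  in one environment** (the aerated pond's 0.06) is only weakly
  identified: the constrained REML estimate runs to the $r=1$ boundary in
  roughly a third of replicates (profile checks confirm these are genuine
  constrained optima, not optimizer failures), and the mean of replicate
  estimates sits about 0.1-0.2 above a generating value of 0.50 even
  though a control with balanced heritabilities of 0.3 recovers its
  generating correlation without bias.  The single-dataset standard error
  (about 0.3) matches what the motivating experiment reported, so this is
  the estimator's honest finite-information behaviour, not a defect —
  but it means the *mean* of cross-environment estimates at these
  components is not an unbiased recovery of the generating correlation.

One further consequence of the small default noise scale deserves
emphasis: the per-fish deviation variance is then tiny (about
$e^{-5.7}$), so even a sub-percent error in the estimated exponent leaves
a lack-of-fit curvature in the linearised residuals that can dominate the
generating noise and shift the location (and compress the genetic signal)
of LnVar_ind computed through the full estimate-then-linearise pipeline.
Analyses of the indicator's *genetics* on synthetic data should therefore
either linearise with the generating exponent or, as the validation suite
does, draw the log-variance trait directly from the animal model.  Real
data, with their much larger absolute deviation scale, are insensitive to
estimation error of this size.

# Known limitations

* One record per fish and trait; no repeated-measures residual structures.
* At most two traits per REML fit; no maternal or common-environment
  random effects; no single-step blending of pedigree and genomic
  information.
* The exponent fit assumes a shared intercept across fish (the
  alternative, a shared slope, is available behind a flag).
* Dense linear algebra throughout: comfortable to a few thousand fish,
  not designed for hundreds of thousands.
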