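---
title: "Two-step MR mediation: models, estimators, and design choices"
author: "mrmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step MR mediation: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The problem

Observational associations between a social exposure such as educational
attainment and a disease outcome such as renal failure are vulnerable to
confounding and reverse causation. Two-sample Mendelian randomization (MR)
sidesteps both by using genetic variants as instrumental variables: variant
effects on the exposure come from one GWAS, variant effects on the outcome
from another, and the causal effect is inferred from the relationship
between the two sets of per-variant coefficients. When the exposure's effect
is partly transmitted through modifiable intermediates (adiposity, smoking,
blood pressure), a *two-step* MR design quantifies how much of the total
effect each mediator carries — which is where intervention opportunities
live, since the exposure itself is often fixed by the time disease risk
materializes.

`mrmediate` implements this workflow end to end on GWAS summary statistics:
instrument selection, allele harmonization, the univariable estimator suite,
multivariable MR (MVMR) for exposure-adjusted mediator effects, a three-step
mediator screen, and delta-method mediation quantification. A built-in
generator simulates multi-trait summary statistics under a known structural
model, so every stage is testable against ground truth without access to
real GWAS files.

## Structural model and estimands

The generator and the mediation analysis share one structural model on
standardized scales (per SD of each quantitative trait; log-odds for the
binary outcome):

* variant $j$ affects the exposure with coefficient $\gamma_j$;
* exposure affects the mediator with coefficient $\beta_{EM}$;
* mediator affects the outcome with coefficient $\beta_{MO}$;
* exposure affects the outcome directly with coefficient $\theta$.

The total effect is $\theta_{tot} = \theta + \beta_{EM}\beta_{MO}$, the
indirect (mediated) effect is $\beta_{EM}\beta_{MO}$, and the mediated
proportion is their ratio. `true_total_effect()` and
`true_mediated_proportion()` expose these identities so simulation studies
can score estimates against truth:

```{r truth}
sc <- causal_scenario(theta_direct = -0.30, beta_EM = -0.29, beta_MO = 0.293)
true_total_effect(sc)
true_mediated_proportion(sc)
```

## Estimators

**IVW.** The primary estimator combines per-variant Wald ratios
$r_j = \hat\beta_{out,j}/\hat\beta_{exp,j}$ with inverse-variance weights
$w_j = \hat\beta_{exp,j}^2/se_{out,j}^2$, equivalent to weighted least
squares of outcome on exposure coefficients through the origin. The standard
error is multiplicative random-effects:
$se_{fixed}\cdot\max\{1,\sqrt{Q/(n-1)}\}$, so heterogeneity can widen but
never narrow the interval. We chose the random-effects form because the
analyses this package targets routinely show significant Cochran's Q while
retaining IVW as the primary model; the truncation at 1 makes the test
slightly conservative under perfect homogeneity (measured rejection ≈ 4.5%
at nominal 5% in the package's calibration tests).

**MR-Egger.** Weighted regression *with* intercept after orienting all
exposure coefficients non-negative. The slope is robust to directional
pleiotropy under the InSIDE assumption; the intercept estimates the mean
pleiotropic effect. Inference uses the regression t reference distribution
with $n-2$ degrees of freedom, the convention of regression-based MR
software.

**Weighted median.** Wald ratios are ordered and interpolated at half the
normalized inverse-variance weight mass; consistent while valid instruments
carry more than 50% of the weight. No closed-form standard error is in
common use, so the package uses a seeded parametric bootstrap (default
1,000 replicates) resampling both coordinates of every variant from their
sampling distributions.

**Radial MR.** The IVW regression re-expressed on radial coordinates; the
slope is algebraically identical to IVW (tested to 1e-10), and each
variant's contribution $Q_j$ to Cochran's Q is referred to $\chi^2_1$ with
an unadjusted per-variant $\alpha = 0.05$, the radial convention.

**MR-PRESSO.** Leave-one-out residual sums of squares with a simulated null:
a global pleiotropy test, per-variant two-sided empirical outlier p-values
(Bonferroni-adjusted, flagged at adjusted $p<0.05$), an outlier-corrected
IVW estimate, and a distortion test comparing the corrected-vs-full
difference with random same-size subsets (1,000 seeded draws). Simulation
counts default to 1,000 and are configuration-exposed; the methods' original
conventions are retained because the mirrored analyses name the tests
without tuning details.

**MVMR.** Weighted least squares of outcome coefficients on the matrix of
exposure coefficients without intercept; each coefficient is a direct
effect conditional on the other exposures. Instruments are the union of the
per-exposure selections, re-clumped across exposures by distance with the
best minimum p-value winning — the defensible default where the mirrored
analyses do not state their construction. MVMR-Egger adds an intercept
after orienting rows so the first exposure's coefficients are non-negative
(the orientation convention must be fixed somewhere; it is keyed to the
first listed exposure and documented).

## The mediator screen

`screen_mediator()` encodes a three-step qualitative filter:

1. **Unidirectionality.** The exposure must affect the mediator, and a
   nominally significant reverse (mediator-to-exposure) IVW estimate is
   disqualifying *unless* its MR-Egger intercept indicates the reverse
   signal is driven by directional pleiotropy — in that case the reverse
   effect is discounted. This mirrors how bidirectional screens are applied
   in practice: a pleiotropy-contaminated reverse estimate is not evidence
   of true reverse causation.
2. **Consistency.** The mediator must affect the outcome with the same sign
   before and after adjusting for the exposure.
3. **Direction.** The indirect path (product of step-1 and step-2 signs)
   must act in the direction of the total effect.

A zero total effect voids the decision with an explicit reason rather than
silently failing.

## Mediation quantification

For a single mediator the indirect effect is the product
$\hat\beta_1\hat\beta_2$ (exposure→mediator UVMR; mediator→outcome MVMR
adjusted for the exposure), with first-order delta SE
$\sqrt{\hat\beta_2^2\sigma_1^2 + \hat\beta_1^2\sigma_2^2}$. The
second-order cross-term $\sigma_1^2\sigma_2^2$ is available behind
`cross_term = TRUE`; it is negligible at GWAS precision and omitted by
default, matching standard two-step MR practice. For several mediators
jointly, the indirect effect is the difference between the UVMR total and
the MVMR direct effect of the exposure. The mediated proportion divides the
indirect by the total effect, with a delta-method SE that treats numerator
and denominator as independent — defensible across non-overlapping panels,
and a documented limitation otherwise (see below). Proportions outside
$[0,1]$ are returned with a `suppression` flag rather than clipped.

## The synthetic-data generator

`simulate_gwas()` draws summary statistics directly on the standardized
scale — no individual-level genotypes — because two-sample MR consumes only
summary data. Key choices:

* **Effect sizes.** Per-variant exposure effects are half-normal (effect
  alleles oriented to the exposure-increasing allele, the GWAS convention;
  this also gives directional pleiotropy a well-defined sign) and rescaled
  so $\sum_j 2\,\mathrm{eaf}_j(1-\mathrm{eaf}_j)\gamma_j^2$ equals
  `h2_exposure` exactly.
* **Noise.** Observed coefficients add Gaussian noise with
  $se = 1/\sqrt{2\,\mathrm{eaf}(1-\mathrm{eaf})\,n}$; allele frequencies
  are Uniform(0.05, 0.95). Sample overlap between panels is modelled as
  equicorrelated noise with coefficient `overlap_rho`.
* **Binary outcome.** Outcome effects are simulated directly on the
  log-odds scale against a user-supplied *effective* sample size, avoiding
  commitment to any liability-scale model; the mapping from a case/control
  imbalance to an effective n is left to the user.
* **Geometry.** Variants sit ≥ 2 Mb apart on chromosomes 1–22, so distance
  clumping is exercised while instruments stay independent by construction;
  LD, genotype-level simulation, and winner's-curse modelling are
  explicitly out of scope.
* **Defaults.** The default scenario mirrors the education→adiposity→renal
  failure analysis the package is patterned on: exposure GWAS N = 766,345
  with instruments explaining 1.84% of variance, mediator GWAS N = 681,275,
  outcome effective N = 2×10⁵, 150 exposure variants plus 50
  mediator-specific variants explaining 5% of mediator variance (a typical
  genome-wide-significant yield for an anthropometric trait), and effects
  $\theta = -0.30$, $\beta_{EM} = -0.29$, $\beta_{MO} = 0.293$, i.e. a true
  total log-odds effect of −0.385 (OR ≈ 0.68) with 22% mediated.

The generator reproduces the *statistical* structure of multi-trait GWAS
summary data, not its genomic texture: no LD, no allele-frequency spectrum,
no population stratification, no winner's curse beyond what selection on
the simulated p-values induces. Passing tests therefore demonstrate
correctness of the estimators and the pipeline's plumbing under the stated
model, not robustness to everything real data can do.

## Calibration and problem sizes

The package's test suite checks, among other properties:

* IVW type-I error at the null scenario (no causal paths) over 1,000
  simulation seeds, and the Egger intercept's type-I error under balanced
  pleiotropy added to the same null backbone, with pleiotropic effect SD
  0.007 — the RMS per-variant outcome effect the causal scenario would
  produce, i.e. pleiotropy "as large as the signal". Both sit near 5%.
* Parameter recovery and the mediated proportion's CI coverage over 500
  seeds of the default scenario.
* Weighted-median robustness with 40% invalid instruments, planted-outlier
  detection for MR-PRESSO, and uniformity of the PRESSO global p under a
  clean null (500 seeds × 500 simulated replicates).

These problem sizes keep the full suite under a minute on one CPU while
leaving Monte-Carlo error well below the tolerance of each check.

## Numerical choices and degenerate inputs

* 95% CIs use the fixed multiplier 1.959964 everywhere.
* Clumping ties in p are broken lexicographically by variant id, making
  selection independent of input row order.
* Coordinates are 1-based; a candidate within `window_bp` (boundary
  inclusive) of a kept variant on the same chromosome is discarded.
* Palindromic variants are always dropped in strict mode; there is no
  frequency-based rescue, matching the mirrored analyses' unqualified
  removal rule.
* Empty selections, zero shared variants, all-outlier PRESSO sets,
  zero exposure coefficients in a Wald ratio, rank-deficient MVMR designs,
  and zero total effects in mediation all raise explicit errors naming the
  offending quantity; pipelines abort with the stage name attached.
* All stochastic routines (bootstrap, PRESSO simulations, the generator)
  take explicit seeds and restore the caller's RNG state.

## Known limitations

* **LD.** Distance-only clumping replaces r²-based pruning; real data with
  long-range LD needs an external LD-aware pre-filter. Proxy-variant lookup
  is likewise not implemented; variants missing from a panel are dropped
  and logged.
* **Conservative proportion CIs.** The proportion's delta SE assumes the
  indirect and total estimates are independent, but they share the outcome
  panel and part of the instrument set, so their errors are positively
  correlated and partially cancel in the ratio. Measured coverage in the
  default scenario runs slightly above nominal (≈ 96–97%). The same
  direction of error comes from the `max(1, ·)` truncation in the
  random-effects SE.
* **Egger under combined stress.** With a strong causal slope *and*
  pleiotropic variance well above sampling variance, the intercept test's
  multiplicative dispersion model misweights variants and its type-I error
  rises above nominal (≈ 7% in the harshest configuration we measured).
  Calibration claims are therefore stated at the null backbone.
* **Screening is qualitative.** The three-step screen applies fixed
  significance thresholds; it does not control any family-wise error rate
  across candidate mediators.
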