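---
title: "Modelling cerebral small vessel disease as a latent construct: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cerebral small vessel disease as a latent construct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `svdlatent`, the
assumptions it makes, the numerical choices in the implementation, and the
design of the synthetic cohort generator — including what passing the test
suite does and does not establish about real data.

## The measurement problem

MRI markers of small vessel disease (SVD) — regional perivascular-space
(PVS) counts, periventricular and subcortical white matter hyperintensity
(WMH) volumes, regional microbleed (MB) presence, and white-matter
fractional anisotropy (FA) and trace (TR) — are noisy, partially redundant
readouts of underlying vascular pathology. The package models them with a
common-factor model on the correlation scale,

$$\Sigma = \Lambda \Phi \Lambda^\top + \Psi,$$

where binary MB indicators enter through a liability-threshold formulation:
an MB flag is 1 when a standard-normal latent liability, itself loaded on
the factors, exceeds the quantile matching the marker's prevalence. This is
why the pipeline estimates a *mixed* correlation matrix — Pearson between
continuous pairs, tetrachoric between binary pairs (the ML estimate of the
latent-normal correlation with thresholds fixed at the marginal quantiles),
and biserial between mixed pairs. All three estimate the same latent-scale
correlation under the model, so the factor analysis operates on a coherent
matrix.

Key assumptions: multivariate-normal latent structure behind the markers
(checkable only indirectly on real data), monotone marker/liability
relations, and — after the preparation step — approximately linear
correlations among prepared indicators.

## Variable preparation

`prepare_markers()` z-scores continuous markers and dichotomizes MB counts.
WMH volumes (and intentional physical activity) are first passed through
the Tukey ladder of powers: the power is chosen from
$\{-2, -1, -\tfrac12, 0, \tfrac13, \tfrac12, 1, 2\}$ to maximize the
normal-quantile correlation of the transformed sample (λ = 0 means log).
Volumes are strongly right-skewed — summarized by medians and IQRs, and
generated log-normally here — and Pearson correlations computed on raw
log-normal variables with a log-scale SD above 1 are attenuated by 40% or
more, which would corrupt every downstream stage. Normalizing before
z-scoring is therefore treated as part of the pipeline's definition of a
"prepared" marker, not an optional nicety. Transformation parameters are
recorded so the identical mapping can be replayed on new data.

## Factor analysis choices

* **Extraction.** Minimum residual (minres): minimize the sum of squared
  *off-diagonal* residuals of $R - \Lambda\Lambda^\top$ over the
  uniquenesses, with the loadings obtained from the eigen-decomposition of
  the reduced matrix at each step. No inversion of $R$ is needed, which
  matters because matrices containing tetrachoric blocks need not be
  positive definite. Start values are squared multiple correlations from
  the smoothed matrix; optimization is L-BFGS-B on uniquenesses bounded to
  $[10^{-4}, 1]$ with objective tolerance near machine precision. A stalled
  line search is accepted as converged only when the KKT projected gradient
  is below $10^{-3}$ (uniquenesses of pure-noise variables sit on the
  boundary, where the raw gradient need not vanish).
* **How many factors.** Velicer's MAP (average squared partial correlation
  after removing k principal components; minimize over k) and the very
  simple structure criterion (fit of the complexity-1/2 simplified
  loadings; maximize). VSS receives a parsimony plateau rule: the smallest
  k within 0.005 of the maximum is reported, because on noiseless implied
  matrices extra factors yield strictly positive but vanishing gains, so a
  bare argmax over-extracts. When the two criteria disagree, MAP governs
  and a warning is emitted.
* **Pruning.** Indicators with communality below 0.2 are removed one at a
  time (lowest first, ties broken lexicographically), re-estimating the
  mixed matrix and the minres solution after each removal.
* **Rotation.** Oblimin (direct quartimin, γ = 0, gradient-projection
  algorithm) first; when every inter-factor correlation is below 0.32 in
  magnitude (under 10% shared variance) the factors are treated as
  orthogonal and the varimax solution is adopted. The threshold is strict:
  exactly 0.32 retains the oblique solution.
* **Salience.** Loadings of magnitude ≥ 0.32 are salient (inclusive rule;
  the boundary case is configurable).
* **Extension analysis.** Pruned variables are projected onto the factor
  space as $\Lambda_{ext} = R_{ev} W$ with $W$ the regression score
  weights. These are covariances with the estimated factor scores, whose SD
  equals the score validity, so salience of extension loadings is assessed
  against 0.32 × validity.
* **Scores.** Regression method, $W = R^{-1}\Lambda\Phi$; eigenvalue
  smoothing (floor $10^{-6}$, renormalized to unit diagonal, iterated so
  the floor holds after renormalization, entry changes capped at 0.05) is
  applied only where inversion is required — KMO, score weights — never in
  the minres objective itself.
* **Sign/order conventions.** Factors are ordered by explained variance
  (mean squared loading) and oriented so the largest-magnitude loading is
  positive; under this convention FA's loading on the SVD factor is
  negative, as it should be (less anisotropy = more damage). Comparisons
  across solutions align columns greedily on absolute Tucker congruence and
  then fix signs.

## Structural model

The SEM engine uses the RAM parameterization
$\Sigma(\theta) = F(I-A)^{-1}S(I-A)^{-\top}F^\top$ with analytic gradients
(each free parameter perturbs $\Sigma$ by a rank-2 matrix, so the gradient
of the ML discrepancy is a set of inner products). Fitting minimizes
$F_{ML} = \log|\Sigma| + \mathrm{tr}(S\Sigma^{-1}) - \log|S| - p$ and
reports $\chi^2 = (n-1)F_{ML}$, CFI, RMSEA (0 at df = 0 by convention), and
SRMR on the correlation-standardized residuals.

Design decisions:

* **Identification.** Latent disturbance variances are fixed to 1 with all
  loadings free, so the completely standardized solution (computed from
  model-implied variances) is the natural reporting scale.
* **Scale equivariance.** Optimization always runs on the correlation
  scale; because every observed variable carries either a free residual
  variance or a saturated exogenous moment, the model is scale-equivariant
  and the raw-scale ML solution is recovered by rescaling
  ($\theta_{ij} \mapsto \theta_{ij} \, s_i / s_j$ for paths,
  $s_i s_j$ for covariances). This sidesteps the badly conditioned
  optimization that mm³-scale volumes would otherwise cause.
* **Exogenous blocks.** Covariates (and the exposure) are exogenous; their
  variances and covariances are fixed at the sample moments — their ML
  estimates under a saturated exogenous block — and counted as estimated
  moments in the df. Covariates send paths to every endogenous structural
  variable (SVD, GM volume, cognition); with cardiovascular risk as the
  exposure, sex is dropped from the covariate set because the risk score is
  already sex-specific.
* **Residual covariances.** Indicator pairs sharing a modality (PVS–PVS,
  WMH–WMH, FA–TR) get free residual covariances for shared method variance.
  In the generator these arise exactly as products of second-factor
  loadings, so the default mediation model is correctly specified for the
  synthetic data.
* **Heywood handling.** Residual variances are bounded below at $10^{-6}$;
  hitting the bound raises a flagged warning.
* **Optimization.** L-BFGS-B with analytic gradients, PCA-informed loading
  starts, and up to three deterministically jittered restarts on
  non-convergence.
* **Effect decomposition.** All directed exposure→outcome paths are
  enumerated on the acyclic structural graph; each pathway effect is the
  product of its standardized coefficients. Total = direct + total
  indirect and total indirect = Σ pathways hold to 1e-12 by construction.
  Proportions mediated are reported in percent and flagged undefined for a
  zero total effect.
* **Bootstrap.** Bias-corrected (BC, not BCa — no acceleration term)
  nonparametric case resampling: $z_0 = \Phi^{-1}(\#\{\hat\theta^* <
  \hat\theta\}/B)$ shifts the percentile endpoints. Reference scale is
  5000 resamples; the coverage test uses 500 resamples × 200 replicates,
  a deliberately scaled-down design whose Monte-Carlo error the assertion
  accounts for.
* **Invariance.** Multi-group ML with equality constraints: configural
  (latent variance fixed to 1 in every group), metric (shared loadings;
  latent variance freed in groups 2..G), then equal residual variances plus
  equal latent variance (residual covariances stay group-specific; no mean
  structure, so no classic scalar level). With six sites and six
  indicators this gives df = 36 / 61 / 96. The main engine is plain ML —
  the synthetic data are multivariate normal — but the Satorra–Bentler-type
  scaled difference formula is implemented and unit-tested against hand
  arithmetic so externally supplied robust scaling factors can be used;
  with unit scaling it reduces to the plain likelihood-ratio difference.
  Negative scaled differences are floored at zero with a warning.

## Association models

Cognitive outcomes are regressed on factor scores (or individual markers)
with Gaussian identity-link GLMs under three nested covariate sets:
demographics/design (age, sex, race/ethnicity, education, site, ICV,
language, MRI-to-testing interval and order), plus vascular risk factors,
plus APOE ε4. Confidence intervals invert the profile likelihood (offset
refits, deviance cut at the 95% χ²₁ quantile) — for Gaussian models these
agree with t-intervals to well under 1% of a standard error, which the
tests verify against the closed form. Multiplicity across individual-marker
analyses is controlled by Benjamini–Hochberg FDR within each cognitive
domain.

## The synthetic cohort generator

`generate_cohort()` emulates the study conditions end to end: two
orthogonal marker factors with the canonical loading pattern; MB flags by
liability thresholding at prevalences 24/14/8% (lobar/deep/infratentorial);
raw scales matching the reference cohort profile (basal ganglia PVS
63.3 ± 16 counts, FA 0.393 ± 0.025, ICV 1,358,887 ± 145,867 mm³, ...); WMH
volumes log-normal with the reference medians and IQRs; covariates drawn
independently of the latent factors (no joint covariate–marker distribution
is available to emulate; independence is a flagged default with an
opt-in site-shift hook for invariance power experiments); a ten-test
cognitive battery with loadings 0.65 on latent cognition, whose means are
rescaled so the population PCA composite has mean −0.72 and SD ≈ 2.19; and
standardized structural paths whose pathway products equal the reference
mediation effects (−0.043, −0.007, −0.018 for age; −0.021, −0.007, −0.002
for cardiovascular risk). The split of each product between its
coefficients is not identified by those targets, so the symmetric
square-root convention is used (mediator paths equal in magnitude) — a
documented synthetic convention, not an estimate.

Two deliberate departures from the canonical loading pattern:

* The generator's thalamus-PVS loading is (0.48, 0.18) rather than the
  canonical (0.42, 0.16), which puts the thalamus communality at
  0.202 — exactly at the 0.2 pruning threshold — so a generator using it
  as the population value would retain or prune thalamus PVS by a coin
  flip at n = 892. The canonical pattern remains available in
  `default_marker_loadings()` and is what the recovery experiments use.
* MB liability loadings (0.26, 0.33 with 0.05 on factor 2, 0.29) are tuned
  so the four weak indicators are pruned with high margin while preserving
  the intended pruning order (lobar weakest, deep strongest) and keeping
  deep MB the extension-analysis standout; a deep-MB population communality
  near 0.19 would itself be threshold-adjacent and unusable.

Counts are rounded and floored at zero in raw units. For insular PVS
(mean 5.8, SD 5.1) the flooring introduces a small truncation bias in
raw-scale moments and correlations; the exact factor structure lives on the
z scale, which `generate_indicators()` exposes directly and which the
correlation-convergence checks and large-n recovery experiments use.

## What the tests establish — and what they don't

The suite verifies internal correctness (estimators against independent
oracles: quadrature grid search for tetrachoric, simulation for biserial,
hand-computed partial correlations for KMO, closed-form profile-likelihood
endpoints, brute-force FDR step-up), exact recovery on noiseless implied
matrices, parameter recovery at large n, bootstrap coverage and test size
at their nominal levels, and end-to-end determinism. Problem sizes were
chosen as the smallest that make the Monte-Carlo error budget meaningful:
n = 100,000 for EFA loading recovery, n = 50,000 for SEM recovery (within
3 asymptotic SEs), 200 replicates for coverage and test size, 500 bootstrap
resamples per replicate.

None of this validates the substantive model on real data: the generator is
multivariate normal with MCAR-only missingness, has no scanner effects
beyond an optional site shift, no covariate–marker confounding by default,
and takes normalized cognitive scores as given. Passing tests show the
machinery does what it claims under the stated model, not that the model is
true of any cohort.

## Known limitations

* Only binary categorical indicators (no polychoric for ordinal variables).
* No robust (sandwich) standard errors; robust scaling factors for the
  invariance tests must be supplied externally.
* Covariance-only SEM (no mean structure, hence no scalar invariance
  level).
* Listwise deletion is the only missing-data strategy beyond the pairwise
  option in the correlation builder.
* The Tukey ladder's grid and normal-quantile criterion are one reasonable
  operationalization of "ladder of powers"; both are configurable.
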