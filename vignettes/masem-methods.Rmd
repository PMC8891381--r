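---
title: "Methods: two-stage meta-analytic SEM for the support–stress–QoL triangle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage meta-analytic SEM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(masem3)
```

This vignette is the package's own account of the statistical machinery:
the two-stage model, its assumptions, the parameters that matter, the
numerical choices, what the synthetic generator does and does not
emulate, and the known limitations.

## The problem and the data

Parents of young autistic children report high parenting stress and
reduced quality of life; perceived social support is a candidate
protective factor. The package operates on a coded study table: one row
per reported Pearson correlation between two of the three constructs —
social support (SS), parenting stress (PS), quality of life (QoL) —
with its sample size, optional scale reliabilities, and study-level
moderators (parent role, support instrument, QoL focus, sociocultural
background, mean child age). The packaged table
(`asd_parenting_studies()`) holds 44 correlations from 31 independent
samples; studies that reported only subdimension correlations were coded
with the composite-score formula implemented in
`composite_correlation()`, which is exact for unit-weighted composites
given the mean within-construct intercorrelations.

## Stage 1: pooling and heterogeneity

Correlations are pooled on the Fisher-z scale, where the sampling
distribution is approximately normal with variance $1/(n-3)$. The
fixed-effect estimate is the inverse-variance weighted mean; the
random-effects estimate uses DerSimonian–Laird weights
$1/(v_i + \hat\tau^2)$ with the method-of-moments
$\hat\tau^2 = \max\{0, (Q - (k-1))/(\sum w - \sum w^2/\sum w)\}$.
Model choice (`select_model()`) is the conventional disjunction: random
effects when the Q test is significant at $\alpha = 0.05$ or
$I^2 > 75\%$. Estimates and Wald intervals are back-transformed with
$\tanh$, which keeps interval bounds inside $(-1, 1)$ and guarantees
the pooled value lies in the convex hull of the inputs.

DL is the only $\tau^2$ estimator offered: it is what the analysis this
package systematizes used, and offering REML or Paule–Mandel variants
would change none of the package's conclusions while complicating exact
reproduction. The confidence multiplier is fixed at 1.959964.

Rosenthal's classic fail-safe N uses per-study standard normal deviates
$Z_i = z_i\sqrt{n_i-3}$ and defaults to a two-tailed $\alpha = 0.05$
criterion, which reproduces the published counts for this dataset; the
one-tailed variant (the default of some older software) is available via
`tails = 1`.

Stage-1 pooling operates on the correlations *as coded*. The
attenuation correction (`disattenuate_r()`) can be switched on per call
(`attenuate = TRUE`, substituting 0.8 where a study reported no
reliability), but the default is off: measurement error is handled once,
structurally, in Stage 2, and the published Stage-1 tables are
reproduced only by uncorrected pooling.

### Moderators

Categorical moderators are tested by the between-group Q statistic on
the level-pooled means, $Q_B = \sum_j W_j(\bar z_j - \bar z)^2$ with
$W_j$ the inverse squared standard error of level $j$'s pooled mean.
Within-level pooling defaults to DL random effects — the mixed-effects
subgroup analysis. This was a genuinely open design point: the fully
fixed partition has the elegant identity
$Q_{total} = Q_B + \sum_j Q_{W,j}$ (exposed, and tested, via
`pool_within = "fixed"`), but the mixed variant is what reproduces the
published moderator table exactly (instrument Q = 5.482, role
Q = 4.438, QoL-focus Q = 5.558), so it is the default. Records with an
unreported moderator are dropped from that moderator's analysis, never
imputed, and the drop count is reported. Moderator p-values are
reported raw, with no family-wise correction, matching standard
practice in this literature; users comparing many moderators should
adjust downstream.

Continuous moderators use weighted least squares of z on the covariate:
a first fixed-weight pass yields the residual $Q_E$, the
method-of-moments residual $\hat\tau^2$ follows, and the reported slope
comes from the re-weighted fit — the standard DL mixed-effects
meta-regression (it agrees with `metafor::rma(method = "DL")` to
machine precision, which the test suite checks). Effects are regressed
as *signed* values exactly as coded. This resolves an ambiguity in the
source analysis: its positive child-age slope (0.037) on negative
correlations is reproduced exactly by the signed convention, which
therefore means the support–stress correlation *weakens* in magnitude
as children age — the sign conventions matter and are left to the
caller to interpret.

## Stage 2: the latent mediation model

`pooled_matrix()` assembles the three pooled correlations into a 3×3
matrix and carries per-construct mean reliabilities (study means with
0.8 substituted where unreported — a deliberately conservative
convention) and per-cell study counts and total sample sizes. The
matrix must be positive definite before any fit; this is checked at
construction.

Each construct is a single-indicator latent variable with fixed loading
$\sqrt{\rho}$ and fixed error variance $1-\rho$, so the structural
model estimates relations among disattenuated constructs. For the
saturated (partial-mediation) model this is algebraically equivalent to
ordinary regression algebra on the disattenuated matrix, which gives
the closed forms in `mediation_closed_form()` — the independent oracle
against which the ML optimizer is verified to $10^{-6}$ on random
matrices.

The ML discrepancy is minimized by BFGS from the closed-form start,
with residual variances parameterized on the log scale (which enforces
positivity and keeps line searches inside the admissible region; an
indefinite implied matrix during a line search simply returns a large
penalty). Convergence tolerance is $10^{-12}$ on F. The correlation
matrix is treated as a covariance matrix of standardized variables —
the convention of the SEM software this pipeline mirrors — with no
Wishart correction for analyzing correlations; the reported paths are
standardized via the fitted latent variances, which for a saturated fit
on a correlation matrix coincide with the raw parameters.

The test statistic is $\chi^2 = (N-1)F_{min}$ at the fitting sample
size $N$. Because the cells rest on different numbers of participants,
$N$ defaults to the harmonic mean of the three cell totals
(4,189.8 for the packaged table). The source analysis never printed its
$N$; back-solving its printed $\chi^2$ and RMSEA suggests a value near
4,150, so $\chi^2$ and RMSEA agreement can only be expected to a few
percent, and `n =` accepts any explicit value. The saturated model has
six free parameters against six moments (df = 0, $\chi^2 = 0$, exact
reproduction of S); dropping the direct path gives df = 1 and, on the
packaged matrix, $\chi^2 = 533.4$ — decisive evidence against full
mediation.

The Monte Carlo (parametric bootstrap) mediation test samples the path
vector from its joint asymptotic normal distribution — covariance
$\frac{2}{N-1}H^{-1}$ with $H$ the numerical Hessian of F at the
optimum — and takes percentile intervals of $a\cdot b$, $c'$ and
$c' + ab$. Default 20,000 draws; the seed is a required argument and
the caller's RNG stream is saved and restored. Fewer than 1,000 draws
triggers a warning because extreme percentiles are then unstable.

### Group comparison

`multigroup_compare()` fits the saturated model per group, then refits
with one path constrained equal across groups; CMIN is the
constrained-minus-free $\chi^2$ on one df. Two conventions were open
here. First, per-group $N$: the harmonic mean of that group's own cell
totals, the same rule as the pooled fit. Second, reliability: group
matrices are fitted *raw* by default. The published group path
coefficients equal the raw closed-form paths of the printed group
matrices exactly, and under the raw + harmonic-mean convention the
published CMIN values (0.736, 16.447, 7.878) reproduce to three
decimals — so that is the default, with a global measurement layer
available via `reliability =` for users who have group-invariant
reliability estimates.

## The synthetic generator

`simulate_studies()` draws study sets from a known truth: per study and
per cell, a true latent Fisher-z equal to the population value plus
$N(0, \tau_z^2)$ heterogeneity (plus any moderator shift), attenuation
by $\sqrt{\rho_x\rho_y}$, then $n$ trivariate-normal observations and
their sample Pearson correlations, of which the study "reports" a
random or prescribed subset. Studies whose attenuated matrix is not
positive definite are redrawn, not clipped — clipping would bias
correlations toward zero — and the redraw count is reported.

The defaults emulate the packaged table: 31 samples, sizes uniform on
the observed range 25–1,384, cell-reporting probabilities
(0.74, 0.29, 0.39) equal to the observed 23/9/12 profile over 31
samples, true paths and reliabilities set to the fitted Stage-2 values,
and $\tau_z = 0.12$, about the middle of the three per-cell DL
estimates (0.147, 0.124, 0.086). Moderator effects act additively on
the z scale — the same scale on which the moderation module estimates
them, so recovery is directly interpretable.

What the generator does **not** emulate: non-normal raw data,
item-level missingness, correlated heterogeneity across cells of the
same study, publication-bias selection, and reliability varying across
studies. Passing recovery tests therefore demonstrates internal
consistency of the pipeline under its own assumptions, not robustness
to their violation.

### Calibration regimes, decided up front

`parameter_recovery()` scores bias, SD, RMSE, interval coverage and the
rejection rate of the full-vs-partial $\Delta\chi^2$ test over
replicates. Two regimes matter:

* *Bias* is assessed under heterogeneity ($\tau_z = 0.1$, 50 studies of
  n = 500 in the reference configuration): point estimates are
  consistent there, up to the small $\tanh$ nonlinearity
  ($|\mathrm{bias}| < 0.02$).
* *Coverage of the Monte Carlo interval* and *type-I error of the
  $\Delta\chi^2$ test* are assessed at $\tau_z = 0$. This is a
  statistical necessity, not a convenience: the two-stage convention
  fits at a fixed N derived from total cell sample sizes, so the
  implied precision matches the true sampling precision only under
  homogeneity. With $\tau_z > 0$ the harmonic-mean-N convention
  overstates precision, intervals undercover and the $\chi^2$ reference
  distribution fails — a known limitation of univariate two-stage
  MASEM (multivariate approaches that propagate Stage-1 uncertainty
  exist, and are out of scope here). The same caveat applies to the
  published standard errors this package reproduces.

Problem sizes used by the test suite (200 replicates for bias, 500 for
coverage and type-I, 20–40 for structural checks) were chosen so the
binomial/Monte Carlo error of each check sits well inside its assertion
band.

## Degenerate inputs and tie-breaks

* $|r| \ge 1$, $n < 4$, duplicate study–sample–relationship keys and
  out-of-vocabulary moderators are rejected at load with the offending
  row named; an empty table loads (with a warning) to an empty dataset.
* Disattenuation past $|r| = 1$: scalar correction clamps with a
  warning; matrix-level correction errors (the latent model is then
  inadmissible); the generator redraws.
* $k = 1$ cells pool as fixed-effect singletons; random-effects pooling
  refuses $k < 2$; between-group tests refuse fewer than two non-empty
  levels and warn on single-study levels.
* A path fixed at zero (full mediation) propagates a degenerate
  point-mass interval for the direct effect rather than an error.
* $\Delta\chi^2$ is floored at zero, and comparing a model with itself
  returns (0, 0, p = 1).

## Known limitations

Stage-1 cells are pooled univariately, ignoring the within-study
covariance of correlations that share a sample. The fixed-N Stage-2
inference understates uncertainty under heterogeneity (see above). The
model family is deliberately the three-construct recursive triangle —
no general SEM graphs, multiple indicators or mean structures. And the
packaged table reflects its source's coding choices (e.g. first
time-point of longitudinal studies), which the loader documents but
cannot re-audit.
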