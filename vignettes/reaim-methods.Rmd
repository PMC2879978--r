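---
title: "Scoring multisite programs with revised RE-AIM indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring multisite programs with revised RE-AIM indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reaim)
```

## The evaluation problem

A weight-management benefit offered by a large insurer is delivered at
dozens of approved fitness, rehabilitation and hospital sites. Its phase I
is a 12-week intervention (site-based exercise, diet therapy, behavior
therapy); phase II spans the rest of the first year and functions as a
maintenance benefit. An evaluation has to answer five distinct questions —
reach, effectiveness, adoption, implementation, maintenance — from two
very different data sources: participant-level measurement records and
site-level implementation surveys. `reaim` turns those records into the
five RE-AIM indices and three composite impacts.

## Index model

Every index is a product of components bounded in [0, 1], scaled by 100.
Differential ("negative") components enter as `(1 - effect)` multipliers:

* `R = IPR (1 - DR) 100`, where IPR is enrollees over the estimated
  eligible membership and DR averages the sex and age representativeness
  effect sizes;
* `E = ICR_1 O_1 (1 - DI_1) 100`, completion x outcome x differential for
  phase I; the same formula with phase-II components gives `M_I`;
* `A`, `I`, `M_S` are plain rates x 100 (sites adopting over potential
  sites; mean protocol components delivered over 14; continuing sites over
  sites old enough to assess);
* impacts are pairwise products over 100.

Two design properties motivate the formula shape. First, subtracting
differential effects (the older convention, kept available in
`legacy_indices()`) can produce negative, uninterpretable indices whenever
the differential term exceeds the positive one. Second, effect sizes whose
range exceeds 1 can do the same. The revision uses only effect sizes
bounded by 1 (squared Cramér phi, partial eta squared) and multiplies by
their complement, which makes non-negativity a theorem: the test suite
checks it over 10,000 random component vectors.

## Effect sizes

**Squared Cramér phi.** For an r x c table,
`phi_c^2 = chi^2 / (n (min(r, c) - 1))`, with Pearson's chi-square and no
continuity correction (the sample sizes here make the plain Pearson
statistic the natural choice; no exact tests, no multiplicity correction).
Benchmarks: ~.01 small, ~.09 moderate, >.25 large.

**Partial eta squared from two timepoints.** The outcome model is a
repeated-measures ANOVA on baseline and end-of-phase weight. With exactly
two timepoints the within-subject decomposition is a function of the change
score `d = followup - baseline`, and the implementation uses those
closed-form identities: ungrouped, `F_time = t^2` of the paired t-test and
`eta2_time = t^2 / (t^2 + n - 1)`. With a between-subjects factor (sex, or
age group) the model is a mixed ANOVA fitted with the unweighted-means
(Type III) convention — marginal means weight the group means equally and
sums of squares use the harmonic mean of the group sizes — because the
groups are strongly unbalanced (on the order of 1,000 women vs 270 men) and
weighted sums of squares would let the majority group absorb the time
effect. The sex and age differential impacts come from *separate*
one-factor models, and DI is their unweighted mean; general k-timepoint or
multi-factor designs are out of scope. The test suite cross-checks the
decomposition against a brute-force cell-means computation and against the
one-way unweighted-means ANOVA on change scores.

Degenerate inputs: fewer than 3 complete pairs or a singleton group is an
error; zero variance at both timepoints returns zero effect sizes with a
`degenerate` flag rather than 0/0.

**Descriptive summaries.** Biomedical measurement distributions here are
mostly right-skewed, so summaries switch style on the adjusted sample
skewness (the SPSS/SAS estimator): |skewness| > 1 reports median (IQR),
otherwise mean (SD). The threshold of 1 is a convention chosen once;
quartiles use linear interpolation between order statistics
(`stats::quantile` type 7) so fixtures are bit-reproducible.

## Component computation and overrides

`reaim_evaluate()` computes every component from a `cohort_dataset`:
phase-wise completion among phase-eligible records (enrolled at least 84
days, resp. 365 days, before data collection — both inclusive; the
12-week window is interpreted as 84 days since no day-level rule is given
by the program), outcome and differential effect sizes from the weight
model, and the site components from approval dates, component checklists
and continuation status. Missing cells are excluded listwise per analysis,
so each statistic uses its own maximal complete subset.

Any component can instead be supplied as an override, and the provenance
log records which values were computed versus supplied. This matters for
one component class in particular: published representativeness values
cannot generally be reconstructed from printed marginals, because the
comparison-population convention (participants versus non-participants,
versus the full eligible pool; table layout; rounding of the eligible
counts) is rarely stated. `representativeness_phi2()` implements one
documented convention — participants versus remaining eligibles, eligible
counts rounded — and flags its output as convention-dependent; evaluations
that must match a published table pass the published effect sizes as
overrides.

## Rounding conventions

Components display at 3 decimals and indices at 1 decimal. Impacts are, by
default, computed from the 1-decimal-rounded factor indices
(`compute_impacts(round_indices = TRUE)`): printed impact values in
evaluation tables are products of printed indices, and full-precision
products can differ in the last decimal (5.385 x 43.838 / 100 = 2.36 prints
as 2.4 from 5.4 x 43.8, but 2.3 unrounded). Internal computation is full
precision throughout; only the impact step applies print-precision factors,
and `round_indices = FALSE` turns it off.

## The synthetic cohort generator

The generator exists because the source data live in a proprietary
insurance database. It emulates the statistical structure the analysis
assumes, with defaults fixed at the study conditions:

* **Enrollment bias**: 80.0% female against a 54.1%-female eligible pool;
  age-group weights (.01, .08, .23, .40, .24, .04) over the six bins
  `[18,25) ... [65,Inf)`, concentrating enrollment at 45-54.9 years with
  very few under-25 or 65+ enrollees. The six ten-year half-open bins
  starting at 18 are the minimal scheme consistent with the reported
  groupings, and are configurable.
* **Skewed baselines**: weight is log-normal per sex, with mu = log(median)
  and sigma = log(q75/q25) / (2 z_.75) solved from the target median and
  IQR (women 220.8, IQR 192.0-258.4 lb; men 269.9, IQR 232.7-333.8 lb).
  Heights and the secondary measures (blood pressure, body fat, waist) are
  normal per sex, with per-measure missingness rates approximating the
  observed missingness pattern.
* **Attrition**: completion is Bernoulli given sex — phase I .748 (women) /
  .837 (men); phase II is drawn conditionally on phase-I completion at
  `p2/p1` so that .395 / .514 are the *marginal* rates among
  phase-II-eligible enrollees. Enrollment dates are spread so 1,647 of
  1,952 enrollees are phase-I-eligible and 762 phase-II-eligible in
  expectation. The generator supports per-age-group completion adjustments,
  but the default leaves them at zero: only marginal sex rates are
  identified by the available summaries, so the joint sex-by-age structure
  is product-form by assumption (a documented limitation).
* **Skewed weight change**: change from baseline is `location - Gamma(shape
  2, scale)`, with scale matched to the target IQR width and location to
  the target median per sex and phase (phase I: -12.0 lb women, -16.9 lb
  men). The gamma kernel reproduces the long loss tail of the observed
  change distributions. An `interaction_magnitude` knob shifts the male
  change location by an additional amount, inducing a controllable
  sex-by-time interaction; 0 adds nothing beyond the per-sex locations.
* **Sites**: 31 sites of four types; each of the 14 protocol components is
  an independent Bernoulli with probabilities summing to 12.8 (nine
  components always delivered, home exercise logs the weakest at .65);
  18/31 of sites are mature (approved at least a year before collection)
  and continue with probability 14/18.

A single seed drives everything; each generated block (demographics,
dates, baselines, completion, changes, secondary measures, missingness,
sites) draws from a sub-stream derived deterministically from it, so adding
a block never perturbs earlier draws and a fixed seed reproduces the cohort
byte for byte.

What the generator does **not** emulate: site-level random effects in
attrition or outcomes (only marginal rates are calibrated), monthly
measurement trajectories (only the three analysis timepoints exist),
informative missingness, measurement error correlated within site, and any
dependence between baseline weight and completion. Pipeline tests passing
on synthetic cohorts therefore demonstrate correctness of the statistical
machinery under the calibrated marginal structure, not fidelity to every
joint feature of real claims data.

## Problem sizes and numerical checks

The convergence checks run the generator at n = 20,000 (realized completion
within ±0.02 of its targets), the null-interaction check uses 20 seeds at
n = 3,000 (interaction eta^2 < .01), and parameter recovery uses a 3-point
grid of induced shifts at n = 4,000 — sizes chosen to put Monte Carlo error
well inside the tolerances being asserted. ANOVA oracle equivalence is
checked to 1e-9 relative on 50 random small fixtures (n <= 12, up to 3
groups), where a brute-force decomposition from cell, subject and grand
means is computed independently.

## Limitations

The engine scores a program; it does not test hypotheses about it (no
confidence intervals on indices — point values only, as the framework
defines them). Representativeness is convention-dependent (above). The
eligibility estimate inherits the coarseness of its prevalence inputs, and
the BMI-consistency check is a flag rather than a rejection because
measurement protocols legitimately vary by site.
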