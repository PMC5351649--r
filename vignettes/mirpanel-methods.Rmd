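---
title: "Methods: risk-score miRNA panels from qRT-PCR data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: risk-score miRNA panels from qRT-PCR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirpanel)
```

`mirpanel` models a four-phase circulating-miRNA biomarker study: a pooled
qPCR screen, per-sample verification, absolute quantification in training
and testing cohorts, and fixed-cutoff transfer to an external cohort. This
vignette documents the statistical model, the parameters that matter, the
numerical conventions, and — importantly — what the synthetic checks can and
cannot say about real plasma data.

## Quantification model

qPCR reports a cycle threshold Ct, which is linear in the log of template
abundance. Two quantification routes are supported:

* **Absolute.** A dilution series of a synthetic miRNA mimic is fitted by
  unweighted ordinary least squares, `Ct = intercept + slope · log10(conc)`,
  with concentration in fmol/L. The amplification efficiency is
  `10^(−1/slope) − 1`; a perfect doubling per cycle gives slope
  `−1/log10(2) ≈ −3.32` and efficiency 1. Unknowns are inverted through the
  curve (`ct_to_concentration()`). No outlier rejection or weighting is
  applied: dilution series are short (5–7 points) and curated by the
  operator, and a weighting scheme would add a silent degree of freedom.
* **Relative.** `delta_delta_ct()` computes per-sample
  `ΔCt = Ct(target) − mean Ct(references)` and reports `2^−ΔΔCt`. The
  calibrator is the **control-group mean ΔCt**, a choice the workflow makes
  deliberately: it makes the control-group geometric mean exactly 1, which
  is how published exosome/tissue tables with control means near 1 are
  naturally read. When several reference assays are given (e.g. the spike-in
  combined with miR-16), their Cts enter as an arithmetic mean — equivalent
  to a geometric mean of the linear quantities, the standard convention for
  multi-reference normalization.

Sample-to-sample extraction and RT variation is removed by
`spike_in_normalize()`: the exogenous cel-miR-39 spike-in is added to every
sample at a fixed amount, so any deviation of its Ct from the reference is a
per-sample technical offset, subtracted from every assay. The operation is
idempotent, and the ΔΔCt pipeline is invariant to any per-sample global Ct
shift (the offset cancels), which the test suite checks as properties.

Undetected wells are represented as `NA` throughout. `censor_undetected()`
maps late wells (Ct ≥ 40, the protocol's cycle count) to `NA`; the
no-template negative control is deliberately excluded from censoring,
because an `NA` negative control would *lift* the detection-gate margin
rather than enforce it.

## Screening filters

The phase-1 gates mirror the panel workflow:

* **Detection gate:** Ct < 37 (strict) and at least 5 cycles below the
  negative control (inclusive — "5 lower" is read as a margin of ≥ 5; the
  boundary case passes).
* **Pool gate:** each case pool versus the single control pool must show a
  fold change above 2 (up) or below 1/2 (down) *in every pool*; mixed
  directions fail. Screening-phase expression is relative, `2^−ΔCt` against
  the global mean Ct of the detected assays (the panel-style normalizer);
  the normalizer set is configurable.
* **Verification gate:** group fold change > 1.5 or < 0.66 *and*
  Mann–Whitney p < 0.05, two-sided.

Pooling is modelled as equal-volume mixing, so a pool's concentration is the
arithmetic mean of its members. Matrix effects of physically pooled plasma
are not modelled.

## Panel construction

For each marker the ROC of "value > threshold" is scanned over all distinct
observed values. The cutoff maximizes Youden's `J = sens + spec − 1`; ties
break toward higher specificity, then the lower threshold; the reported
cutoff is the midpoint of the optimal gap between adjacent distinct values
(any point of the gap classifies identically, and the midpoint is the
least arbitrary representative). If `J = 0` everywhere the cutoff is flagged
degenerate. Markers whose raw AUC is below 0.5 are treated as
down-regulated: the score is 1 below the cutoff.

The weight `W_j` is the slope of a univariate logistic regression of case
status on the **dichotomized score** — the quantity the risk score function
sums — fitted by Newton–Raphson with step-halving (convergence
`|Δ log-likelihood| < 1e-10`, at most 100 iterations). A continuous-value
alternative is exposed via `build_panel(weight_on = "value")` for
sensitivity analyses. Under complete separation the ML slope diverges; it is
capped at |10| (odds ratio ≈ 2.2·10⁴, beyond any plausible biomarker effect)
with a warning, and the intercept is re-maximized at the capped slope. The
risk score `RSF_i = Σ_j W_j S_ij` gets its own Youden cutoff on the training
cohort, after which `evaluate_fixed()` applies the panel without
re-estimating anything — the frozen-cutoff contract that the validation
stages rely on, enforced by tests.

AUC confidence intervals use the Hanley–McNeil variance by default, with
DeLong's placement-value variance as an option; the empirical trapezoidal
AUC is identical to Mann–Whitney pair counting (concordant + half ties over
`n₁n₀`), a cross-module identity the suite verifies on every random
instance it draws.

## Hypothesis tests

`mann_whitney()` always applies midrank tie correction. For total n ≤ 12 the
two-sided p-value is an exhaustive enumeration over all group assignments
(valid with ties); above that, a normal approximation with tie-corrected
variance and continuity correction. The exact/approximate switch at 12 keeps
enumeration (≤ 924 assignments) trivially fast while matching
`wilcox.test`'s exact p-values where both apply. `paired_t()` is the
classical paired t with n − 1 degrees of freedom; a zero-variance difference
vector is flagged degenerate instead of producing an undefined statistic.
Association with clinical covariates uses a χ² test for dichotomous scores
and one-way ANOVA for continuous values. All tests are two-sided; no
multiplicity correction is applied anywhere, matching the workflow being
modelled (the verification FC+p gate is the only error control).

## The synthetic generator

Concentration tables are drawn from **moment-matched lognormals**:
`mu = ln(m²/√(m²+s²))`, `sigma = √ln(1+s²/m²)`, so the generated mean and SD
equal the targets exactly. The lognormal family was chosen because the
published group SDs are of the order of the means on a nonnegative scale —
strong right skew; a zero-truncated normal is available behind
`family = "truncnorm"`. Between-miRNA dependence is a Gaussian copula with a
configurable Spearman correlation, default 0.3 (circulating miRNAs are
co-regulated and co-extracted, but the true correlation is unrecoverable
from published tables; it is a free simulation parameter, never asserted).
Cohort sizes default to the modelled study's stages: 30/10 screening, 42/32
training, 66/62 testing, 33/30 external.

Simulated Ct matrices invert the quantification path: curve prediction plus
Gaussian measurement noise (default 0.2 cycles, a typical qPCR replicate
SD) plus a shared per-sample offset (default 0.5 cycles) that the spike-in
carries and `spike_in_normalize()` removes exactly. Default curves use slope
−3.32 and intercept 35, placing 1–10⁴ fmol/L in the Ct 21–35 window.

The planted screening phase draws 168 assays with baseline abundances
log-uniform over 10–1000 fmol/L, per-sample log-scale SD 0.3 (CV ≈ 31%,
a realistic combination of biological spread and assay noise for pooled
plasma), 13 up- and 1 down-regulated planted assays, and 10 assays placed
below the quantifiable range to exercise the detection gate. The planted
effect defaults to 4-fold (0.25 for the down-regulated assay). That value is
a design requirement, not an empirical estimate: the planted-recovery checks
require effects that pass *every* gate, and a 4-fold effect leaves the
normalized pool fold change (≈ 3.6 after global-mean normalization shrinks
it) several standard deviations of pool-level sampling noise above the
2-fold gate, while remaining inside the fold-change range published
screening hits actually show. With this margin the cascade recovers exactly
the planted set with no false positives across seeds.

Paired designs (tissue tumour/normal, arterial/peripheral) share a
subject-level random effect within each pair (log2 SD 0.5) under a condition
effect; exosome tables are two independent groups on the 2^−ΔΔCt scale with
published exosome moments as defaults. Note the exosome table's printed fold
changes follow the control/case convention (its control means sit near the
calibrator value 1); `fold_change(direction = "control_over_case")` exposes
this explicitly rather than guessing intent.

## What the synthetic checks do and do not show

The generator reproduces the published *moments*; it does not reproduce the
published *discrimination*. Worked through the closed form
(`expected_auc_lognormal()`), the printed means and SDs under lognormality
imply single-marker AUCs of roughly 0.67–0.87 — systematically above the
published empirical AUCs of 0.61–0.69 for the same markers. Real plasma
concentrations are evidently heavier-tailed (or more contaminated by
pre-analytical variation) than any two-moment lognormal can express, so a
moment-matched cohort separates *more easily* than the real one. The test
suite computes both sides of this gap: large-cohort simulated AUCs converge
to the closed form within Monte-Carlo error (confirming the generator is
faithful to its own model), while the panel-level plausibility check against
the published training AUC band fails high and is retained as a documented
red result. Passing synthetic tests therefore demonstrate the *correctness
of the machinery* — gates, cutoffs, weights, frozen transfer, calibration of
type-I error — not that real-data performance would match.

Also not modelled: hemolysis and other pre-analytical degradation, batch
and plate effects beyond the per-sample spike offset, inter-plate
calibration, and melting-curve specificity.

## Problem sizes and numerical conventions

The shipped checks use sizes chosen to make Monte-Carlo error negligible
relative to their tolerances while staying quick to run: 200 replicates for
the panel and type-I calibration properties (99% binomial bounds on
rejection rates at α = 0.05), 10⁴ observations for logistic slope recovery
(within 10%), 10⁶ draws for lognormal moment recovery (1%/2%), 2×10⁴ per
group for the closed-form AUC comparison (within 3 SE), and 1000 random
instances for the exact AUC/pair-counting identity. Exact identities are
asserted at 1e-12; OLS against the closed-form normal equations at 1e-9.
All generators are bit-reproducible given a seed, and every seed in the
acceptance script derives from its `--seed` argument.

Degenerate inputs are first-class: single-class cohorts, zero control
means, fewer than two distinct dilution concentrations, zero-variance
paired differences, undetected spike-ins and empty covariate levels all
raise informative errors or flagged results rather than silent numbers.

## Limitations

* The RSF is a sum of dichotomized indicators; it discards within-marker
  gradation by design (matching the modelled workflow), so its AUC is a
  step function with few distinct values in small cohorts.
* Youden's J weighs sensitivity and specificity equally; other operating
  points need a different cutoff rule.
* The univariate weights ignore between-marker correlation; a multivariable
  model would weight correlated markers differently (deliberately out of
  scope).
* Fold-change gates on group means are sensitive to heavy tails; the
  verification p-value gate (rank-based) is not, and the two together are
  the intended control.
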