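---
title: "Simulation-based power analysis for ROC curve and AUC studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation-based power analysis for ROC curve and AUC studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aucpower)
```

## The problem

Studies that measure discriminability — how well a test, procedure, or
participant separates signal from noise (old from new items in a recognition
task, patients from controls on a screening inventory) — are usually analysed
with a receiver operating characteristic (ROC) curve and its area under the
curve (AUC). Planning such a study requires a power analysis on the AUC
scale, not on the scale of a t test someone might run instead. `aucpower`
estimates that power by simulation: it generates rating datasets from the
design the researcher expects, analyses each one exactly as the eventual
study would be analysed, and counts how often the resulting confidence
interval supports the conclusion of interest.

Three hypothesis tests are supported, all driven by confidence intervals and
a smallest effect size of interest (SESOI):

* **NHST** — the 95% CI excludes the null value (AUC 0.5 for a single
  curve; 0 for a difference between curves).
* **Minimum-effect test (MET)** — the whole 95% CI lies beyond the SESOI,
  i.e. the effect is not merely nonzero but at least as large as the
  smallest effect worth caring about.
* **Equivalence test (EQ, two one-sided tests)** — the whole 90% CI lies
  inside the equivalence region set by the SESOI, i.e. the effect is too
  small to care about.

## The data model

### ROC curves from rating data

A rating dataset is a set of observations `(label, score)` with
`label = 1` for signal and `0` for noise, and an ordinal confidence score
(higher = more signal-like; the package never flips this direction, so a
sign-reversed effect shows up as one). For each cutoff `c` over the observed
scores,

* TPR(c) = P(score ≥ c | signal) = hits / (hits + misses),
* FPR(c) = P(score ≥ c | noise) = false alarms / (false alarms + correct rejections),

and the ROC curve is the (FPR, TPR) polyline from the most conservative
cutoff to the most liberal, anchored at (0, 0) and (1, 1). The AUC is the
trapezoidal area under that polyline, which for cumulative-threshold curves
equals the tie-corrected rank statistic
P(S_signal > S_noise) + ½ P(S_signal = S_noise) exactly — ties contribute
one half, realised automatically by the trapezoids. The partial AUC over an
FPR interval [a, b] is the same area restricted to the interval, with
linear interpolation at the boundaries, reported raw (no standardisation);
the chance diagonal over [0, t] has area t²/2.

### Inference

For full curves the package uses the DeLong placement-value estimator (in
its midrank form): the variance of the AUC is
`var(signal placements)/m + var(noise placements)/n`, and Wald intervals are
`AUC ± z·SE` with fixed quantiles z = 1.96 (95%) and 1.645 (90%) at
α = 0.05 (recomputed from α otherwise). For an unpaired difference the SE is
`sqrt(V1 + V2)`; this is algebraically the same as deriving the SE from the
unpaired DeLong z statistic but stays well defined at a zero difference,
which equivalence simulations hit constantly. For paired designs the
covariance of the two AUCs is estimated from the paired placement vectors
and subtracted twice.

Wald intervals are **not clamped** to [0, 1]: the decision rules compare
raw bounds, and clamping would bias equivalence decisions near the
boundary. Printing clamps for display only.

Partial-AUC inference uses a stratified percentile bootstrap (cases and
controls resampled separately, class sizes preserved; default 2000
replicates, deterministic given a seed). Replicates that carry no
discrimination information (all resampled scores identical) are redrawn and
counted.

## The generator

Rating data are simulated from a binormal signal-detection model: latent
strengths are `N(mu_noise, sd_noise)` for noise items and
`N(mu_signal, sd_signal)` for signal items (defaults: noise mean 0, both
SDs 1 — the equal-variance model with its symmetric curvilinear ROC;
unequal SDs give the bowed asymmetric shapes). The continuous-data AUC has
the closed form

> AUC = Φ((mu_signal − mu_noise) / √(sd_signal² + sd_noise²)),

which the package exposes as `closed_form_auc()` and uses as the analytic
anchor for everything else. Each participant contributes a fixed number of
signal and noise items; in paired designs the two latent values of an item
are bivariate normal with correlation `rho`, applied to signal and noise
items alike.

### Redistribution onto the rating scale

Latent values are redistributed onto an ordinal 1..K scale (K = 6 by
default, the usual confidence format). The package's default rule is
**equal-frequency (quantile) binning** of the pooled latent values of a
dataset. This choice was made on two grounds: it is a monotone
transformation that preserves within-dataset ranks almost perfectly, so the
ordinal-scale AUC stays close to the continuous AUC; and it reproduces the
standard anchor mapping of the 6-point scale (signal mean 0.38 → AUC ≈
0.60, 0.57 → 0.65, 0.78 → 0.70, 1.0 → 0.75, 0.11 → 0.53). Equal-width
binning of the pooled range is available via `discretize = "equal_width"`
(it compresses the tails and loses 0.01–0.03 of AUC at these effect sizes),
and fixed latent cutpoints via `cutpoints =`, for designs where the mapping
from strength to category is assumed stable across datasets rather than
adapted to each sample.

### What the generator does and does not emulate

The generator reproduces the design quantities a power analysis needs:
class sizes, items per participant, latent effect size, pairing
correlation, and the coarsening of the scale. It deliberately does **not**
model participant heterogeneity: a `participant` column is generated and
retained, but observations are treated as independent by every estimator,
exactly as the common practice of aggregating ratings across participants
does. If true data have strong participant-level variation in
discriminability, the simulated power will be optimistic. Latent
distributions are normal only; empirical AUCs are known to be robust to
moderate non-normality, but heavy tails or mixtures are outside this
generator's scope.

## The power loop

`power_config()` validates a design up front (a single-curve SESOI must be
an AUC in (0.5, 1); a two-group SESOI a difference in (0, 0.5]; partial
designs get their SESOI on the raw pAUC scale). `run_power()` then draws one
independent RNG substream per simulated dataset from the master seed, so
runs are reproducible and any single dataset can be regenerated without
replaying the ones before it. For each dataset the design's estimator runs
(DeLong for full curves, stratified bootstrap for partial curves) and the
three decision rules are applied with strict inequalities.

Choices worth knowing about:

* **Orientation.** For two-group designs the difference is oriented so the
  hypothesized effect (the sign of the closed-form AUC difference between
  the two specs) is positive, and the MET rule is one-sided on that
  direction: the lower 95% bound must exceed the SESOI. A dataset whose
  estimate comes out in the wrong direction therefore fails MET — it is not
  silently corrected.
* **Single-curve equivalence region.** For a single AUC the region is
  symmetric about the null: (1 − SESOI, SESOI), e.g. (0.40, 0.60) for a
  SESOI of 0.60. For differences it is (−SESOI, +SESOI). For a single
  partial AUC the null value is the chance-diagonal area
  (hi² − lo²)/2 and the region is symmetric about it.
* **Boundary calibration.** With the true effect exactly at the SESOI, the
  TOST-style EQ rule passes at about the α rate. The one-sided MET rule
  rejects at about α/2 (≈ 2–3% at α = 0.05) rather than 5%; a two-sided
  exclusion rule would give 5% but would also reject for effects *below*
  the SESOI, which contradicts the point of a minimum-effect test, so the
  one-sided rule is used and its boundary rate is simply reported by
  `type1_check()`.
* **Degenerate datasets.** Small designs occasionally produce a simulated
  dataset with zero DeLong variance (e.g. perfect separation). These count
  as `FALSE` for all three decisions — conservative power — and are tallied
  in `n_degenerate` rather than dropped.
* **z quantiles.** At α = 0.05 the Wald quantiles are fixed at 1.96 and
  1.645 (the conventional reporting values) instead of `qnorm(0.975)` and
  `qnorm(0.95)`; the difference is invisible at simulation resolution but
  keeps reported intervals identical to hand-computed ones.
* **Display rounding.** AUCs are reported at two decimals via C-style
  formatting of the underlying double (`sprintf("%.2f", x)`), which is how
  ROC software prints them; all internal computation is at full precision.

### Problem sizes

The package's own test suite exercises the scenarios it is built around:
single-curve runs at 100–200 participants with 2 signal + 2 noise items
each and 1000 simulations; two-group runs at 100 participants per group
with 2–10 items of each kind; and partial-AUC runs over FPR ∈ [0, 0.167]
(the six-person-lineup range) at 200 simulations × 500 bootstrap
replicates. Those sizes give Monte Carlo SEs of about 0.007–0.016 on a
power estimate, which is the resolution at which the reported powers should
be read. Full-fidelity partial runs (1000 × 2000) are reachable through the
configuration but are an order of magnitude slower; the scaled defaults
carry a warning for that reason.

## A worked example

```{r}
worked_example()
```

The packaged two-group frequency table (also in
`inst/extdata/recognition_ratings.csv`) reproduces the canonical worked
analysis: cumulative TPR/FPR tables, trapezoidal AUCs of 0.61 and 0.73 at
two decimals, a DeLong 95% CI of [0.59, 0.64] for the first group, and an
unpaired AUC difference of −0.12.

A power analysis for a design expecting that first group's performance:

```{r}
cfg <- power_config(
  design = "single",
  spec1 = binormal_spec(
    mu_signal = 0.38, n_participants = 100,
    items_signal = 2, items_noise = 2
  ),
  sesoi = 0.60, n_sims = 200, seed = 1
)
run_power(cfg)
```

(1000 simulations is the recommended default; 200 here keeps the vignette
fast.)

## Known limitations

* Participant clustering is ignored by inference (see above); there is no
  mixed-model option.
* Confidence bands along the ROC curve itself are not constructed; the
  package exports curve coordinates for external plotting instead.
* No smoothed or binormal-fitted ROC curves: all curves are empirical.
* No sample-size search: users sweep configurations and read the power
  table, which keeps every reported number attached to an explicit,
  reproducible configuration.
* Exact small-sample or logit-transformed AUC intervals are out of scope;
  intervals are Wald (DeLong) or percentile bootstrap.
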