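---
title: "Operant learning analysis and multidimensional phenotyping: models and methods"
author: "operantPheno"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Operant learning analysis and multidimensional phenotyping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(operantPheno)
```

## What this package computes

`operantPheno` supports preclinical behavioral studies in the
*Ube3a*^m−/p+^ mouse model of Angelman syndrome (AS), where cognitive-like
impairment is measured with an operant acquisition/extinction task and
motor-adjacent impairment with a standard battery (weight, rotarod, open
field, marble burying, nest building). It covers four jobs:

1. **Operant session scoring** — from a per-mouse, per-day session log
   (trials, cued and non-cued nose-pokes, rewards) it derives accuracy,
   days to acquisition criteria, at-criteria response summaries, and
   acquisition-normalized extinction curves.
2. **Multidimensional phenotyping** — z-standardization (optionally within
   sex), PCA, k-means clustering with `k = 2`, genotype-validation
   accuracy, genotype centroids and their distance in two-PC space, and a
   PC1 composite severity score.
3. **Power analysis** — bootstrap Monte-Carlo power of the two-sample
   t-test over a per-group sample-size grid, yielding a per-measure
   minimum-n planning table.
4. **Synthetic cohorts** — a seeded generator that emulates the design of
   a two-genotype (WT, AS), two-sex, two-cohort study, so every stage of
   the pipeline is testable end to end without animal data.

## The synthetic cohort model

### Battery measures

Each battery measure is drawn independently per mouse from

$$y \sim \mathcal{N}\!\left(\mu_0 + \mathbb{1}[\mathrm{AS}]\, d\,\sigma_0
  + \mathbb{1}[\mathrm{F}]\, d_{\mathrm{sex}}\,\sigma_0,\ \sigma_0^2\right),$$

where $(\mu_0, \sigma_0)$ are the control mean and SD in native units and
$d$, $d_\mathrm{sex}$ are standardized genotype and sex shifts
(`effectSpec()`). The default genotype effects are the achieved Cohen's d
values reported for this battery in the AS-model literature (rotarod day 1
1.64, rotarod day 5 1.22, open-field distance 0.07, marbles buried 1.62,
nest building 1.52, with signs encoding the direction of the AS effect);
weight and open-field center time use effects derived from published
genotype F statistics via $d = \sqrt{F\,(1/n_1 + 1/n_2)}$ with group sizes
30 and 26 (`dFromF()`: 40.69 → 1.71 and 0.1391 → 0.10). Control means and
SDs are plausible native-unit values for adult C57BL/6J mice; they only
set the scale and cancel in every standardized analysis. Weight carries a
−1 SD female shift so that sex-split standardization has something real to
remove.

Measures are independent by default because the joint covariance of this
battery is not established; `simulateBattery()` accepts a correlation
matrix (Gaussian copula) for users who want to impose one. Values are
*not* clamped to physical ranges (a marble count can be non-integer), a
deliberate simplification that keeps the sampling model exactly normal so
configured effect sizes are recovered without truncation bias.

### The operant learner

The task protocol fixes the contingencies; the animal is a parametric
stand-in (`learnerParams()`). Expected cued responses on acquisition day
$t$ follow a logistic learning curve
$a / (1 + e^{-r (t - t_0)})$; non-cued responses are a flat rate; counts
are Poisson by default (negative binomial via a `dispersion` option —
published session logs do not constrain the dispersion, so the minimal
choice is the default). Rewards follow the task schedule: the first 10
cued responses each pay (FR1), later rewards require a geometric number of
responses with mean 2 (VR2; the standard realization of a variable-ratio
schedule, which the protocol itself does not pin down). Trials equal
rewards, as a trial is defined by reward receipt. Acquisition runs until
the criteria — strictly more than 15 trials *and* strictly more than 75%
accuracy on five consecutive days — are met, or a 40-day cap is reached;
capped mice are flagged, never dropped. Extinction always lasts three
days with zero rewards; expected day-1 cued responding is `burst_gain`
times the final acquisition expectation and decays by `extinction_decay`
per day. A `primed` flag records the sessions where pellets would be
placed in the apertures (acquisition days 1–2 and any day after a <5-trial
session); priming has no behavioral effect in the model, it is bookkeeping
for log fidelity.

Default WT parameters (asymptote 60, rate 0.50/day, midpoint day 5,
non-cued rate 12, decay 0.50, burst 1.0) produce learning curves that
reach criteria around day 10–12 with ~83% accuracy. The AS defaults
(asymptote 40, rate 0.42, midpoint day 7, non-cued 7, decay 0.45, burst
0.87) were calibrated once, on 500-per-group simulations, so that the
standardized genotype differences on the three planning metrics — days to
criteria, accuracy at criteria, normalized extinction day 1 — land near
the achieved effect sizes 0.84, 0.89 and 0.91 reported for this task,
while reproducing the qualitative phenotype (slower acquisition, fewer
responses but higher accuracy at criteria, steeper day-1 extinction).

What the generator does **not** emulate: between-animal heterogeneity
(all mice of a genotype share one parameter set, so within-group variance
on count-derived metrics is purely Poisson and standardized effects on raw
counts, e.g. cued responses at criteria, come out larger than in real
data); within-session event timing; motivation, body-weight or
food-restriction dynamics; cross-measure correlation. Green tests
therefore certify the *analysis machinery*, not distributional realism of
mouse behavior.

## Operant scoring conventions

Several conventions are underdetermined by published protocols; the
package fixes defaults and exposes each as a parameter:

- **Accuracy criterion.** Protocol descriptions in this literature quote
  the criterion variously as >50% or >75% cued response rate. The default
  is the stricter procedural value, 0.75 (`minRate`), with strict
  inequalities throughout (a day with exactly 15 trials or exactly 75%
  accuracy does not pass).
- **Days to criteria** is the last day of the *first* five-day qualifying
  run — the total number of acquisition days before the mouse advances to
  extinction. Appending post-criteria sessions can never change it.
- **At-criteria summaries** average exactly the five criterion days.
  Accuracy is the mean of daily accuracies by default; a pooled-count
  alternative (`accuracyMethod = "pooled"`) is available since the two
  differ whenever daily totals differ.
- **Extinction normalization** divides each extinction day's cued and
  non-cued counts by the *group mean* at-criteria responding. "Group"
  defaults to genotype, pooling sexes and cohorts (`groupBy` parameter) —
  cohorts that differ in reward pellet size can be separated by passing
  `groupBy = "cohort"`-style groupings. Accuracy during extinction stays
  on raw counts. Normalized day-1 values above 1 represent an extinction
  burst.
- **Missing data.** Mice that never reach criteria propagate `NA`
  at-criteria fields and are excluded from group baselines; nothing is
  imputed.

## Phenotyping choices

- **Standardization** uses the sample SD (n − 1). Measures listed in
  `sexSplit` are z-scored within each sex, removing sex main effects; the
  list can be given explicitly or chosen by `detectSexSplitMeasures()`,
  which flags measures whose sex main effect in a two-way genotype + sex
  linear model has p < 0.05 — mirroring the convention of sex-splitting
  only tests where a sex difference is observed.
- **PCA** is covariance PCA of the z-scored matrix (equivalently,
  correlation PCA of the raw data). No measure-direction flipping is
  applied beforehand — latencies and weights enter as-is — so PC1's
  orientation is meaningful only together with its loading table; the
  sign of each component is fixed by making its largest-magnitude loading
  positive, which makes loading tables reproducible across platforms.
- **Clustering** runs on the first two PC score columns (centroid
  distances are defined in 2-PC space, and clustering in the same plane
  keeps accuracy and distance comparable), squared-Euclidean k-means with
  50 seeded restarts by default. Validation accuracy takes the best of
  the cluster↔genotype label mappings, so it is at least 0.5 by
  construction. Genotype centroids use the *true* genotype labels, not
  the clusters.
- **Severity score.** PC1 of the battery serves as a one-number composite
  severity score (`severityScore()`); `pc1Correlations()` regresses each
  operant metric on it per genotype with OLS, reporting R², the two-sided
  slope p and a 95% confidence band.
- Mice lacking operant metrics are dropped from the operant-inclusive run
  with a logged count (battery-only runs keep all mice).

## Power analysis choices

`estimatePower()` resamples n values per group with replacement from two
source vectors and counts two-sided two-sample t-tests with p < α
(pooled-variance Student t by default; Welch via `var.equal = FALSE`,
since bootstrap conventions differ on this point). When real per-group
data are available they are the natural sources — `runPipeline()`
bootstraps the simulated cohort's own per-genotype vectors. For planning
from a published effect size alone, `normalSources()` builds large normal
sources standardized so their empirical pooled d equals the nominal value
exactly, removing source-level sampling error from the estimate.

The grid is n = 4–30 per group; requirements beyond the grid are reported
with an explicit `">30"` sentinel rather than extrapolated. Raw power
curves at 10,000 iterations carry Monte-Carlo jitter of about ±0.01, which
can make the curve locally non-monotone exactly where it crosses a target;
an isotonic (pool-adjacent-violators) projection is applied before
thresholding. One master seed drives per-(measure, n) sub-seed streams so
any single cell is reproducible in isolation. The closed-form noncentral-t
power (`analyticPower()`, df = 2n − 2, noncentrality $d\sqrt{n/2}$) is
kept in the package as an independent oracle: the Monte-Carlo estimator is
required to agree with it within ±0.03, and under the null to sit within
three binomial standard errors of α.

Note that a minimum-n cell whose smoothed power sits within ~0.005 of the
target (e.g. d = 0.89 at n = 21, analytic power 0.803) can move by one
mouse between seeds; this is inherent Monte-Carlo behavior, not a defect.

## Degenerate inputs and numerical corners

- Accuracy of a zero-response day is undefined; such days can never pass
  criteria, and `responseAccuracy()` refuses them explicitly.
- Zero-variance measures, strata with fewer than two mice, all-identical
  PC positions, zero extinction baselines, and resamples with zero
  variance in both groups each produce a named error or (for the last) a
  logged non-significant iteration — never silent NaNs.
- `nComponents` beyond the matrix rank is refused; rank is assessed at a
  relative tolerance of 1e-8 on the singular values.

## Problem sizes used by the test suite

The shipped tests exercise the statistical claims at sizes chosen to make
Monte-Carlo error small relative to each tolerance: effect-size recovery
at 10^4 mice per group (±0.05 ≈ 3.5 SE), power-oracle agreement and
type-I calibration at 10^4 iterations, sample-size table checks at 10^4
iterations over the full 4–30 grid, and clustering accuracy over 100
replicate 56-mouse cohorts. The whole suite runs in well under a minute.

## Known limitations

- The generator's homogeneity (no per-animal parameter variability)
  inflates standardized effects on raw response counts; conclusions about
  *real* effect sizes should come from real data fed through the same
  functions.
- Power analysis covers the two-group t-test only — no repeated-measures
  or interaction designs, and no multiplicity adjustment.
- `k` other than 2 is a pass-through; validation accuracy with more
  clusters than genotypes falls back to majority-vote mapping.
- The PC1 severity score is orientation-stable but not sign-canonical
  across different measure sets; compare scores only within one feature
  configuration.
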