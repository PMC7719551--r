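---
title: "Decomposing dichromatism evolution: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing dichromatism evolution: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dichroma)
```

## The question and the model

Sexual dichromatism — a color difference between the sexes — can arise
by directional change in male color (the Darwinian route, classically
attributed to sexual selection) or by directional change in female color
(the Wallacean route, classically attributed to natural selection for
crypsis). The two routes produce the same present-day pattern, so
distinguishing them requires reconstructing the history of color change
for each sex separately. `dichroma` does this on a time-calibrated
phylogeny, with each species × sex summarized as a centroid in CIELAB
color space.

CIELAB is used because it is approximately perceptually uniform: the
three axes (lightness `L`, green–red `a`, blue–yellow `b`) share one
perceptual unit, so Euclidean distance (ΔE) means the same thing
anywhere in the space, averages of pixel clouds are meaningful colors,
and no per-axis rescaling is performed at any point — rescaling would
destroy the geometry the whole method relies on. The in-package sRGB →
CIELAB conversion uses the IEC 61966-2-1 matrix with the reference white
taken as the image of RGB white, so neutral grays map exactly onto the
`a = b = 0` axis.

### Phylogenetic ridge regression

For one sex, let `y` be the tip centroids (tips × 3) and `X` the
root-to-tip path design matrix: `X[i, b]` is the length of branch `b` if
it lies on the path from the root to tip `i`, else 0. The model

    y = mu + X beta + e,    minimize ||y − mu − X beta||² + lambda ||beta||²

estimates a rate vector `beta_b` (Lab units per Myr) on *every* branch
and an ancestral state at every node by accumulating `rate × length`
from the estimated root `mu`. A rate per branch is only identifiable
because the penalty shrinks the variance of rates; with `lambda = 0` and
more branches than tips the system is singular (the package refuses it
with a pointer to `lambda > 0`). Unlike Brownian-motion models with a
single rate, this recovers *where* on the tree color changed, which is
what the sex comparison needs.

Numerical route: the intercept is profiled out by centering, one SVD of
the centered design is reused for all penalty values, and leave-one-out
cross-validation (LOOCV) is computed exactly via the `e/(1 − h)`
identity. Ancestral-state path consistency
(`state(child) = state(parent) + rate × length`) holds to machine
precision by construction.

### Choosing the penalty

The penalty is selected by minimizing the exact LOOCV squared prediction
error of tip values on a log-spaced grid scaled to the design's
spectrum, refined by golden-section search — deterministic given the
data. Two sharing decisions matter:

* **One penalty across the three color axes.** The axes share a
  perceptual unit; separate penalties would distort the 3-D geometry of
  the rate vectors.
* **One penalty across the two sexes** (in `decompose_dichromatism()`
  and the permutation machinery). Shrinkage scales rate magnitudes
  directly, so comparing `‖m‖` with `‖f‖` under different penalties
  confounds the biology with the tuning. During development,
  independently selected per-sex penalties occasionally differed by
  orders of magnitude on simulated data and reversed the sign of the
  rate-ratio signal; the joint choice (minimizing the summed LOOCV error
  over all six axis–sex combinations) removes that artifact and makes
  sex-swap symmetry exact. Standalone `fit_rrphylo()` /
  `select_penalty()` still select per fit.

The reference implementation of this family of ridge models does not
publish its selection rule, so equivalence with it is approximate by
construction; the cross-validated choice is the standard, reproducible
default.

### The decomposition

With both sexes fitted, every branch carries the male and female rate
vectors `m`, `f` and the ancestral dichromatism vector at its parent
node, `D = c_m − c_f`. The sign convention is female → male: with it,
the scalar projections

    s_m = m · D̂,    s_f = −f · D̂,    s = s_m + s_f = (m − f) · D̂

make `s` the first-order time derivative of `‖D‖` (positive = the sexes
diverging), `s_m` the male share (male moving away from the female
counts positively), and `s_f` the female share (female moving *toward*
the male counts negatively, hence the minus sign). Three summaries:

* rate ratio `mean‖m‖ / mean‖f‖`;
* OLS of `log(‖m‖/‖f‖)` on ancestral `‖D‖` — its slope is algebraically
  the `dichromatism × sex` interaction of the stacked model, a property
  the tests assert to 1e-10;
* OLS slopes of `s_m ~ s` and `s_f ~ s` (with intercepts). Because
  `s = s_m + s_f` row-wise and OLS is linear in the response, the two
  slopes sum to exactly 1; 0.5/0.5 means equal contributions.

Degenerate geometry is handled explicitly: branches whose ancestral
`‖D‖ < 1e-9` have no defined projection direction, get
`s_m = s_f = s = 0`, are flagged, and are excluded from the contribution
regressions; branches with a rate magnitude below 1e-12 are excluded
from the log-ratio regression (log of zero), with counts reported.
Monochromatic-everywhere data make the contribution regression
degenerate and raise an error rather than returning numbers.

Both "all branches" and "terminal branches only" (`tips_only = TRUE`)
granularities are supported; the per-species reading of the contribution
analysis corresponds to terminal branches, the per-branch reading to all
of them. The branch table always contains every branch.

## Inference

**Permutation test.** Sex labels are swapped within species
independently with probability 0.5; the phylogeny and the colors present
in each clade are untouched, only sex-specific signal is destroyed. The
*entire* pipeline — including penalty re-selection — is rerun on each of
`R` permuted datasets (default `R = 1000`), so the null distribution
reflects every estimation step. Two-tailed p-values use the add-one
rule, `p = (1 + #{|null − c| ≥ |obs − c|})/(R + 1)`, with the statistic
re-centered at its theoretical null value `c`: 0 for the log rate ratio
(i.e., ratios compared on the log scale about 1), 0 for regression
slopes, 0.5 for contribution slopes. Per-replicate seeds derive
deterministically from the master seed.

**Phylogenetic signal.** Pagel's λ for per-species `‖D‖` is estimated by
maximizing the likelihood of an intercept-only model whose covariance is
the Brownian matrix with off-diagonals multiplied by λ (bounded search
on [0, 1], tolerance 1e-6, endpoints checked). The confidence interval
is a percentile interval from a *parametric* bootstrap (simulate from
the fitted model, re-estimate; default `R = 1000`): the bootstrap flavor
is not dictated by the sources the package follows, and the parametric
scheme matches the reference implementation of the λ model and keeps the
tree structure in every replicate.

## The synthetic-data generator

`simulate_tree()` draws a pure-birth (Yule) tree conditioned on the tip
count and rescales it to a root age of 100 Myr — the approximate depth
of the European butterfly radiation this emulates. `simulate_colors()`
evolves colors with, per branch: a shared Brownian increment for both
sexes (`sigma_shared = 3` Lab units per √Myr per axis), independent
sex-specific Brownian increments (`sigma_sex = 1`), and, in scenarios
with drive, a directional displacement of the driven sex
(`drive_strength = 2` Lab units per Myr) along one fixed random unit
direction per driven clade — sustained directional selection toward a
new color, which is what builds persistent dichromatism. Driven clades
are non-overlapping and cover ~30% of tips; 15% of species are forced
exactly monochromatic (their sex-specific components dropped), mirroring
the sizeable monochromatic fraction in real faunas. Defaults were chosen
to resemble the spread of real dorsal color centroids and dichromatism
values; they are documented, tunable inputs, not empirical estimates.

Two deliberate design points: the tree depth matters to recovery, since
the drive is a constant rate while Brownian *rate* noise on a branch
scales as `sigma/sqrt(length)` — on very shallow trees the same
parameters drown the signal; and simulation is internally unbounded,
with colors clipped to the CIELAB gamut box only on output, avoiding
boundary artifacts in rate estimation (at the default scale a minority
of tip coordinates touch the box; the stored ground truth is unclipped).
Darwinian and Wallacean runs with the same seed are exact mirrors (the
random streams are assigned to "driven" and "other" before sexes are
named), which the tests exploit.

What the generator does *not* emulate: measurement error in centroids,
mimicry and other color-function dynamics, selection described by
explicit coefficients, non-Brownian processes (e.g. OU), ultraviolet
reflectance, and within-species polymorphism. Passing recovery tests on
these simulations therefore shows the estimator recovers the *geometry*
it targets under tree-structured noise, not that real butterfly data
satisfy the model.

## Problem sizes used by the test suite

Unit tests run on trees of 3–120 tips. The end-to-end checks use the
documented study scale: scenario recovery at `n_tips = 150` over 20
seeds per scenario; permutation calibration on 200 shared-null datasets
of 64 tips at `R = 99` (a scale-down of the default `R = 1000` that
keeps the p-value grid fine enough for a Kolmogorov–Smirnov check); λ
recovery on 200-tip trees over 20 seeds.

## Known limitations

* **Null spread of the contribution slopes.** Under a shared-evolution
  null with the default noise mix, the across-dataset spread of the
  contribution slope is wide (SD ≈ 0.2 at ~300 branches): `s` cancels
  the shared component exactly, but `s_m − s_f` doubles it, so the
  slope's sampling noise scales with `sigma_shared/sigma_sex` over the
  square root of the effective branch count. This is a property of the
  statistic itself — it persists even when the slope is computed from
  the simulation's ground-truth rates — so single-dataset contribution
  slopes should always be read against their permutation null, not
  taken at face value. The same caution applies to real data.
* The within-species label swap preserves phylogeny and per-clade
  colors, but a permutation null is only as meaningful as its
  exchangeability assumption; statistics not tracked by the study gain
  no protection.
* Rate magnitudes are in Lab units per Myr, which are only as meaningful
  as the color source; comparing two datasets (e.g. drawings vs photos)
  should go through `structure_correlation()`, which correlates pairwise
  color differences and reports per-axis scale slopes.
* The ridge reconstruction shrinks ancestral states toward the root
  mean; near-root dichromatism estimates are accordingly conservative.
* Centroids compress multimodal color patterns to a mean; two
  differently patterned wings with equal mean color count as
  monochromatic. The palette profile (`palette_profile()`) is provided
  for visual inspection of exactly this, but feeds no statistic.
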