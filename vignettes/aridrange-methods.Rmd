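---
title: "Methods: presence-only suitability modeling over arid climate variables"
author: "aridrange"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presence-only suitability modeling over arid climate variables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aridrange)
```

## The problem

`aridrange` estimates the environmental range of a species observed only
where it is present — no absences — in a cold arid mountain landscape, and
asks which combinations of arid-climate variables best describe that range.
The candidate variables are those that define desert (BW) and steppe (BS)
climates in the Köppen–Geiger system: mean annual temperature (MAT, °C),
mean annual precipitation (MAP, mm), and the precipitation of the coldest
and warmest quarters (P_cold, P_warm, mm), with the 6-month winter (ONDJFM)
and summer (AMJJAS) precipitation sums carried alongside for the climate
classification itself. The cold-desert hypothesis is represented by the
variable set {MAT, MAP, P_cold} and the cold-steppe hypothesis by
{MAT, MAP, P_warm}; all 15 non-empty subsets of the four variables are fit
and compared.

## The model

Suitability is modeled with the maximum-entropy (Maxent) formulation of
presence–background estimation. Over a background sample
$x_1,\dots,x_B$ the model is the Gibbs distribution

$$q_w(x) = \frac{e^{w \cdot f(x)}}{\sum_{i=1}^B e^{w \cdot f(x_i)}},$$

where $f(x)$ is a vector of features built from the climate variables. The
coefficients minimize the convex penalized objective

$$J(w) = -\frac{1}{m}\sum_{\text{presences}} w \cdot f(x)
        + \ln \sum_{\text{background}} e^{w \cdot f(x)} - \ln B
        + \sum_j \beta_j |w_j|,$$

whose first two terms are the negative presence log-likelihood relative to
the background and whose L1 term performs feature selection. The fitted
relative occurrence rate ("raw" output) is $q_w$; the cloglog suitability
is $1 - \exp(-e^{H} \, q_w(x))$ with $H$ the entropy of $q_w$ over the
background, which maps raw rates monotonically into $[0, 1]$ (a uniform
model gives the constant $1 - e^{-1} \approx 0.632$).

### Features and regularization

Variables are min–max scaled using constants computed on the background
(the same transform is then applied to presences; values outside the
background range extrapolate linearly — no clamping is applied). Default
feature classes are linear, quadratic, and forward hinge
$\max(0, (z-k)/(1-k))$ at 20 evenly spaced knots $k \in \{0, 0.05, \dots,
0.95\}$; pairwise product features exist but are off by default. This
mirrors the classic automatic feature choice for a few dozen training
presences while keeping the feature count bounded and deterministic.
Per-feature penalties default to $\beta_j = \lambda \, s_j / \sqrt{m}$ with
$s_j$ the background standard deviation of feature $j$ and $\lambda = 1$: a
simple scale-aware analogue of tuned published defaults (reproducing any
specific published $\beta$ table is out of scope).

### Optimization

The objective is minimized by monotone proximal-gradient descent: a
gradient step on the smooth part with backtracking line search, followed by
soft-thresholding for the L1 term. The objective trace is non-increasing
by construction. Iteration stops when the objective improves by less than
$10^{-8}$ (default cap 1000 iterations); if the cap is reached, the fit is
still declared converged when the L1 subgradient (KKT) residual is below
$10^{-3}$, which in practice distinguishes "optimal to numerical noise"
from genuine failure. The fit is deterministic given its inputs.

## The workflow

1. **Thinning.** Occurrences are thinned so every retained pair is at
   least 1 km apart (the cell scale of the ~30 arc-sec grid), by greedy
   removal of the point with the most too-close neighbours, random
   tie-breaking, 100 repetitions keeping the best, and a final
   re-insertion pass that guarantees maximality. On point sets of up to 12
   points the retained count matches the exact brute-force optimum
   (enumeration over all subsets) in every tested case.
2. **Partitioning.** Four train/test splits: seeded random 50/50 (odd
   point to train); training on points strictly above the median
   elevation; and training on the at-or-below-median side of longitude or
   latitude. The side conventions are fixed but configurable: the source
   analyses display the coordinate splits only graphically, so the
   at-or-below side is this package's choice of default.
3. **Background.** 10,000 points are sampled uniformly over the valid
   cells within 400 km (great-circle, spherical Earth R = 6371.0088 km) of
   the thinned points, with replacement, so per-cell counts are a uniform
   multinomial. Sampling is not area-weighted by latitude and presence
   cells are not excluded — both standard presence–background conventions;
   at ~33° N over a 2° extent the cell-area variation is under 2%. One
   shared background serves all 15 models so model comparison is free of
   sampling noise.
4. **Evaluation.** AUC uses the rank-based Mann–Whitney form (ties count
   half). AICc is $-2\ln L + 2K + 2K(K+1)/(n-K-1)$ with $\ln L$ the sum of
   log raw predictions renormalized over the prediction extent, $K$ the
   nonzero coefficient count, and $n$ the thinned occurrence count;
   $n \le K + 1$ is reported unrankable. The maximum-TSS threshold sweeps
   every distinct observed score with rule score ≥ t, maximizing
   sensitivity + specificity − 1; mathematical ties (including float-noise
   ties at $10^{-9}$) break toward the smallest threshold, i.e. the widest
   predicted range.
5. **Categorization.** Cells below the TSS threshold $t$ are unsuitable.
   Within the threshold, the suitability value range $[t, v_{\max}]$ is
   linearly rescaled to $[0,1]$ and carved into nested retentions: high =
   top 30% of the range, moderate = top 70%, low = top 90%, fringe = the
   remainder (exclusive bands [0.7, 1], [0.3, 0.7), [0.1, 0.3), [0, 0.1)).
   "Upper X%" is interpreted on the **value scale**; an upper-X%-of-cells
   (quantile) interpretation is available via `mode = "quantile"` since the
   source description admits either reading. $v_{\max}$ is the observed
   surface maximum, not the theoretical 1.0, so bands are data-adaptive and
   never empty. A surface flat at the threshold classifies all
   within-threshold cells as high, with a warning.
6. **Köppen–Geiger overlay.** The arid threshold is
   $P_{thr} = 2\,\mathrm{MAT}$ when ≥ 70% of MAP falls in ONDJFM,
   $2\,\mathrm{MAT} + 28$ when ≥ 70% falls in AMJJAS, else
   $2\,\mathrm{MAT} + 14$, floored at 0. Arid (B) iff
   $\mathrm{MAP} < 10 P_{thr}$ (strict), desert (BW) iff
   $\mathrm{MAP} < 5 P_{thr}$ (strict), suffix k iff MAT < 18 °C. Both 70%
   tests are evaluated on their own seasonal fraction (winter and summer
   fractions separately), which keeps exact-boundary inputs stable under
   floating point. MAP = 0 with zero seasonal sums uses the intermediate
   branch (fractions set to 0.5), preserving the desert classification of
   true no-rain cells with warm enough temperatures. Hot subtypes
   (BWh/BSh) are computed but folded into "other" in summaries, since cold
   mountain regions never reach MAT ≥ 18 °C.

## The synthetic landscape

Because the original occurrence deposit and the global climate rasters are
external downloads, the package ships a generator whose output has the
statistical structure the workflow assumes; every stage is tested against
it.

* **Terrain and temperature.** Elevation is white noise low-pass filtered
  with a Gaussian kernel (periodic FFT convolution; filter scale a
  parameter) scaled to 2500–6500 m. MAT is a sea-level intercept (33 °C)
  minus a 6.5 °C/km lapse rate times elevation, plus smooth noise — giving
  a landscape MAT distribution centred a little above 0 °C.
* **Precipitation.** MAP is a smooth base gradient (68 + 130·g mm, g a
  smooth field in [0,1]) plus 10 mm per km of elevation (orographic),
  clipped at 30 mm. A smooth cold-fraction field c ∈ [0.2, 0.8] splits MAP
  into P_winter = c·MAP and P_summer = (1−c)·MAP.
* **Quarterly layers.** P_cold and P_warm are sub-fractions of the
  half-year sums with spatially varying fields (means 0.6 and 0.62,
  ±0.15, independent smooth fields). The variation is deliberate: with
  *fixed* sub-fractions, P_warm is an exact deterministic function of
  P_cold and MAP, every variable subset carries the same information, and
  no model-selection experiment can distinguish generating variables from
  proxies. Spatial variation in the sub-fractions is also the physically
  realistic case (the share of a quarter within its half-year varies with
  storm-track position).
* **Truth and presences.** True suitability is
  $\mathrm{logit}^{-1}(b_0 + b_c\,P_{cold}/\mathrm{MAP} +
  b_w\,P_{warm}/\mathrm{MAP} + b_q(\mathrm{MAT} - T^*)^2)$ with defaults
  $b_0 = -3, b_c = 5, b_w = -6, b_q = -0.45, T^* = 2.8$: suitability peaks
  at a high cold-precipitation ratio, a low warm ratio, and MAT near
  2.8 °C. 164 presence cells are drawn proportional to suitability, with
  uniform placement within the cell. The defaults were chosen once so that
  (a) climate at sampled presences approximates the cold arid profile the
  analysis targets (MAP on the order of 130 mm with range within
  60–296 mm, MAT ≈ 2.8 °C, P_cold ≈ 45–55 mm, P_warm ≈ 25 mm), and (b) the
  true-variable model is recoverable (random-split test AUC ≥ 0.85).

What the generator does **not** emulate: real topographic structure
(valley networks, aspect), interannual variability, observation bias along
roads or rivers, and the exact Köppen composition of any real region — on
the default landscape the winter-precipitation fraction at presences often
exceeds 70%, so many presence cells classify as non-arid "other" rather
than the steppe/desert mix a real cold-arid region shows. Passing tests
therefore demonstrate the *mechanics* of the workflow (thinning
optimality, metric correctness, model recovery, categorization algebra),
not field-level realism.

## Verification design and problem sizes

The test-suite and acceptance checks compute every critical quantity twice
by independent routes: Köppen classes against a hand-coded scalar decision
tree on a dense (MAT, MAP, winter-fraction) grid; AUC against explicit
pair counting; the TSS threshold against a naive exhaustive sweep; summary
moments against a two-pass computation; thinning against exact subset
enumeration (n ≤ 12); the 1-D Maxent fit against a grid search with step
$10^{-4}$; haversine distances against an independent geodesy library.
Model recovery runs on the full default scenario (240 × 240 cells, 164
presences, 10,000 background points); the 20-replicate variable-set
discrimination study uses 100 × 100 cells, 2,000 background points, 8
hinge knots, and a scenario generated from {MAP, P_cold} with amplified
MAP variance (base 40, range 220) so that normalization by MAP is
genuinely informative. The replicate criterion is the ranking property:
the generating set or a superset of it outranks every disjoint subset. The
stricter phrasing — the top-ranked set *contains* the generating variables
— is reported but not asserted: a flexible hinge fit of P_cold alone
captures most of a ratio-driven signal, so AICc parsimony legitimately
drops MAP from the top set in a substantial minority of replicates.

## Numerical choices

* Cell assignment is half-open: a point on a shared edge belongs to the
  east/south cell; a $10^{-9}$-cell guard makes decimal edge coordinates
  (float-fuzzy by one ulp) deterministic.
* Distances are great-circle on a sphere (R = 6371.0088 km); no projection
  is chosen at these latitudes.
* Nodata in any layer masks the cell in all layers; no imputation.
* Raw predictions renormalize over whichever domain is in use (background
  for fitting and the cloglog transform; the full valid extent for AICc).
* Thinning tie-breaks are seeded uniform choices; the best of `reps`
  repetitions is kept, so results are reproducible given the seed.
* Statistics with unmet sample-size requirements (sd with n < 2, skewness
  with n < 3 or zero variance) are NA, never 0. Skewness is the moment
  estimator $g_1 = m_3/m_2^{3/2}$ (no small-sample adjustment),
  configurable in principle by post-processing; the source tables do not
  name their estimator.

## Limitations

* No reprojection: input rasters must already share one geographic grid.
* The exact regularization tables, clamping, and bias-file machinery of
  the original Java Maxent are intentionally not reproduced; coefficients
  and AICc values are therefore comparable across models *within* this
  package but not numerically against other implementations.
* The greedy thinning is exact only at oracle scale; for large inputs it
  is a (repetition-boosted) heuristic, as in the established thinning
  tools.
* Category maps depend on the TSS threshold, which is itself a statistic
  of one background sample; a different background seed shifts band
  boundaries slightly.
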