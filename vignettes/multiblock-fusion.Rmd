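---
title: "Multi-block PLS-DA for fused vibrational spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-block PLS-DA for fused vibrational spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specfuse)
```

`specfuse` implements one complete chemometric workflow: per-modality
preprocessing of MIR, NIR and Raman spectra of the same specimens,
damaged-vs-normal classification by one-block and multi-block PLS-DA, grouped
cross-validation, and model interpretation through block weights, regression
coefficients and correlation loadings. This vignette records the statistical
model, the parameter choices and their rationale, the numerical conventions,
and what the synthetic study generator can and cannot stand in for.

## The classification model

Let $X$ be an $n \times p$ matrix of preprocessed spectra and
$y \in \{0, 1\}^n$ the class code (0 = normal cartilage, 1 = damaged). PLS-DA
here is NIPALS PLS1 on centered data: with $X_c = X - \bar{x}$,
$y_c = y - \bar{y}$, each component $a = 1, \dots, A$ extracts

$$w_a = \frac{X_c' y_c}{\lVert X_c' y_c \rVert}, \qquad
  t_a = X_c w_a, \qquad
  p_a = \frac{X_c' t_a}{t_a' t_a}, \qquad
  q_a = \frac{y_c' t_a}{t_a' t_a},$$

followed by deflation $X_c \leftarrow X_c - t_a p_a'$. The response is a
single 0/1 column rather than a two-column class-membership dummy; for two
classes the variants are affinely equivalent, and PLS1 keeps every object a
vector. $y$ is never deflated (redundant for one response). Regression
coefficients are assembled through $b = W (P'W)^{-1} q$, accumulated
incrementally so the nested coefficient vectors of all models with
$1, \dots, A$ components come out of a single fit — cross-validation curves
over the LV count cost one fit per fold. Prediction is
$\hat{y} = \bar{y} + (X_{\mathrm{new}} - \bar{x}) b$, classified as damaged
iff $\hat{y} > 0.5$; a score exactly at the threshold goes to class 0,
deterministically. The threshold is fixed — no operating-point tuning.

Channels are mean-centered but not autoscaled: SNV and the Frobenius block
scaling already control scale, and channel-wise autoscaling would inflate the
noise-only channels produced by derivative preprocessing.

### Multi-block fusion

Blocks measured on the same specimens are fused by scaled concatenation:
each preprocessed block is divided by its Frobenius norm
$\lVert X_b \rVert_F$ (computed over uncentered training entries), the scaled
blocks are concatenated, and one PLS1 model is fitted on the super-matrix.
This is the MB-PLS variant whose super-scores equal the concatenated-PLS
scores: a single normalisation step and one global score vector per LV. The
per-LV importance of block $b$ is the squared-norm share of the super-weight,

$$\mathrm{bw}_{b,a} = \frac{\sum_{j \in b} w_{a,j}^2}{\lVert w_a \rVert^2},$$

which is non-negative and sums to 1 over blocks for every LV. Multiplying
any input block by a positive scalar changes nothing downstream — that
invariance is the purpose of the scaling and is enforced by test.

Whether blocks should be centered before the norm is computed is not
settled in the field; `specfuse` uses the uncentered norm. Inside
cross-validation, norms are always recomputed from the training rows of the
current fold and applied as fixed divisors to the held-out rows, so no
test-row information reaches the fit.

## Preprocessing

Five stages are supported — clipping, Savitzky–Golay smoothing/derivation,
SNV, trimming — applied per spectrum (no information crosses rows). The
per-modality defaults are the parameterisations used in the cartilage
study:

| modality | derivative | SG window (channels) | SG polynomial | SNV | trim (cm⁻¹) |
|----------|-----------:|---------------------:|--------------:|-----|-------------|
| MIR      | 2          | 201                  | 3             | yes | 900–1800    |
| NIR      | 0          | 5                    | 3             | yes | 4545–8333   |
| Raman    | 1          | 205                  | 3             | yes | 800–1800    |

Conventions and their reasons:

* **Stage order** is clip → derive/smooth → SNV → trim (configurable,
  recorded in block provenance). Deriving on the wide untrimmed axis keeps
  the large filter windows away from the edges of the analysis window; the
  cost is that after trimming, row means are no longer exactly zero (SNV
  ran on the wider axis), which is immaterial after centering in the model.
* **Derivatives are taken with respect to channel index**, not cm⁻¹: the
  windows are stated in channels, and a constant axis-spacing factor is a
  row-constant scale later removed by SNV/Frobenius scaling. Edge channels
  are evaluated from the polynomial fitted over the nearest full window
  (the `signal::sgolay` projection matrix), so output length equals input
  length and polynomials up to the fit order are reproduced exactly
  everywhere.
* **SNV** divides by the sample standard deviation ($n - 1$), fixing the
  convention `[1, 2, 3] → [-1, 0, 1]`; the alternative $n$ denominator
  differs by a row-constant factor that the block scaling removes anyway. A
  constant spectrum has no defined SNV image and raises an error naming the
  offending row.
* **Trimming** keeps the closed interval and normalises descending printed
  bounds (NIR windows are conventionally printed high-to-low). **Clipping**
  defaults to no regions; the hook exists for spike/detector-edge removal.
* **Replicates** (three spectra per specimen) are preprocessed individually
  and then averaged into one row per specimen, because model rows must be
  specimens for leave-one-joint-out CV to be well defined. Whether the
  original analyses averaged before or after preprocessing is not
  documented anywhere we know of; averaging after is the safer default
  (preprocessing is nonlinear), and both orders are available through the
  functions.

## Cross-validation and model selection

`run_cv()` implements leave-one-joint-out CV: one fold per joint, all
specimens of the joint (damaged and adjacent controls) held out together.
This respects the strongest dependence in the design — within-animal
correlation — and is the reason the sample unit is the specimen, not the
replicate spectrum. Per fold, Frobenius norms and centering means come from
training rows only; a fold whose training set degenerates to a single class
raises an error naming the joint.

The LV count $A^\*$ minimises the out-of-fold misclassification rate, with
ties broken toward fewer components; minimising the RMSE of the continuous
scores is available as an option (`select_metric = "rmse"`). Selection is
performed on the same cross-validation that is reported (non-nested), which
matches how a single "LV\*" per model family is conventionally reported but
carries a modest optimism; the fold structure itself remains leakage-free.
Percentages are rounded to integers only in `report()`; every upstream
object keeps raw fractions.

A caution for hypothesis-style reading of CV accuracy: out-of-fold
classifications within one fold share a fitted model and a centering
offset, so they are positively correlated and the accuracy of a grouped CV
is noticeably overdispersed relative to a binomial count at the number of
samples — its effective sample size sits between the number of folds and
the number of samples. Chance-level bands computed from a binomial at
$n$ samples are therefore too narrow for this statistic; the package's own
null checks bound the mean accuracy and guard fold construction instead of
asserting binomial bands on single runs.

## The synthetic study generator

`generate_study()` emulates the structure of the cartilage experiment: 10
joints, each contributing 6 damaged and 6 adjacent control specimens
(60 + 60), damaged specimens split evenly into subgroups M1 (impact), M2
(abrasion), E1 (collagenase 24 h), E2 (collagenase 90 min), E3 (trypsin),
three replicate spectra per specimen, and three modalities. One specimen
can be excluded from all blocks (`drop_sample()`), reproducing the
59-damaged/60-control sample sizes of the fused analyses.

Each replicate spectrum is a sum of Gaussian bands with a linear baseline,
multiplicative scatter and i.i.d. channel noise:

$$s(\nu) = m \sum_k a_k e^{-(\nu - c_k)^2 / 2 w_k^2} + b_0 + b_1 \nu +
  \varepsilon(\nu), \qquad
  a_k = \mathrm{base}_k + \delta_k \, \mathrm{class} \cdot \mu_{g} + u_j.$$

Defaults, chosen once as a realistic emulation:

* **Axes**: MIR 400–4000 cm⁻¹ and Raman 200–3400 cm⁻¹ at 0.25 cm⁻¹
  spacing (matching the FTIR digital spacing of ~0.24 cm⁻¹, so that the
  201/205-channel filter windows span a physically sensible ~50 cm⁻¹); NIR
  4000–10000 cm⁻¹ at 6 cm⁻¹ (its window is 5 channels).
* **Bands**: the discriminative bands ($\delta_k \neq 0$) sit at the
  wavenumbers reported as distinguishing damaged cartilage — MIR 1740
  (ester), 1655/1564 (amides), 1245 cm⁻¹ (amide III); NIR 4726 and
  4829 cm⁻¹; Raman 1004, 1250 and 1665 cm⁻¹ — surrounded by stable tissue
  background bands (collagen proline 856/938, CH₂ 1448, carbohydrate
  1060–1080, CH stretches 2850–2940, amide A 3300 cm⁻¹, NIR water/CH
  overtones). The background density matters: real tissue spectra are
  dense in bands, so a class shift in one band barely moves a spectrum's
  SD; a sparse simulated spectrum would let SNV turn the whole mean shape
  class-informative, an artefact rather than a feature.
* **Magnitudes**: replicate noise SD 0.02 (intensity units), class effects
  $|\delta_k|$ 0.08–0.15 (at least five times the noise SD — the clean
  separability consistent with the strong reported discrimination), joint
  effect SD 0.05, scatter factor U(0.9, 1.1), baseline offset ±0.05 and
  slope ±2×10⁻⁵ per cm⁻¹. The within-specimen replicate variance relative
  to between-specimen variance is not documented for the real data; these
  values are assumptions made for testability.
* **Subgroup multipliers** scale $\delta$ per damage subgroup (E1 = 1.5,
  others 1.0), making severe collagenase damage the strongest deviation —
  the configuration the correlation-loading interpretation should single
  out. The multiplier map is config-level and applies to all bands.
* **Joint effect** $u_j$: one additive amplitude shift per (joint,
  modality), shared by every specimen of the joint — the minimal structure
  under which leave-one-joint-out CV differs from leave-one-specimen-out.
* **Hierarchical seeding**: every draw runs under a sub-seed derived from
  (study seed, modality, joint/specimen/replicate indices), so removing a
  specimen never changes another specimen's draws, and a fixed seed gives
  bit-identical studies.

The ground truth exposes, per modality, the channels within two widths of
any discriminative band; interpretation tests measure recovery against it.

What the generator does **not** emulate: within-class biological
heterogeneity (damage severity varies continuously in real tissue — the
generator's classes are cleanly separated, which is why cross-validated
accuracies on the default study saturate near 100% while real-tissue
accuracies sit in the 70–95% range), instrument drift between sessions,
cosmic-ray spikes, fluorescence backgrounds beyond a linear baseline,
water-vapour interference, and any radiative-transfer/ATR penetration-depth
physics. Passing tests on synthetic studies therefore validate the
*machinery* — preprocessing contracts, leakage-free CV, fusion invariances,
band recovery — not clinical performance.

## Interpretation outputs

`unscaled_block_coefficients()` slices the super-matrix coefficients by
block and divides by the block norms, giving vectors that apply to
preprocessed-but-unscaled spectra; their concatenation reproduces the
model's predictions exactly (tested to 1e-10). `select_peaks()` takes the
local extrema of $|b|$ per modality (strict neighbour comparison; a plateau
counts once, at its leftmost channel) and keeps the top $k$ by magnitude,
accepting candidates greedily in decreasing order and skipping any within
`min_separation` (default 10 cm⁻¹) of an accepted band — on finely sampled
axes, noise otherwise yields clusters of quasi-duplicate extrema on a
single band's flank. `k_per_block` defaults to 12, the order of magnitude
of labelled bands per modality in published correlation-loading plots.

`correlation_plot_table()` correlates each selected channel and one 0/1
dummy per damage subgroup with the global scores $(t_1, t_2)$. The dummies
are supplementary — correlated post hoc, never refit — because the model is
trained on damaged-vs-healthy only. Global scores are used rather than
block scores (the published plots are global-level); a block-score variant
can be had by fitting `fit_mbpls()` on a single block. Points with
$r_1^2 + r_2^2 < 0.25$ fall inside the inner reference circle and are
flagged as not well explained by the first two LVs; a zero-variance
variable (e.g. an absent subgroup) has no defined correlation and is
reported as missing, never as zero.

## Numerical conventions and degenerate inputs

* NIPALS stops early if the deflated covariance $X'y$ vanishes (relative
  tolerance 1e-12); the remaining nested coefficient vectors repeat the
  last informative one and `n_lv_effective` records the shortfall.
* Score orthogonality holds to 1e-8 of the trace; SNV idempotence to
  1e-10; fusion scale-invariance to 1e-8 — all asserted in the test suite.
* Ties: LV selection breaks toward fewer components; classification at
  exactly 0.5 goes to class 0; plateau peaks take the leftmost channel.
* Errors are raised (never silently repaired) for: even or oversized SG
  windows, constant spectra under SNV, empty trim windows, zero-norm
  blocks, single-class responses, misaligned row keys across blocks,
  unknown sample ids, and single-class training folds (naming the joint).

## Problem sizes

The default study is 120 specimens × 3 replicates across three blocks of
14401 (MIR), 1001 (NIR) and 12801 (Raman) channels, reduced by trimming to
3601/632/4001 before modelling; the full seven-family cross-validated
analysis of one study runs in well under a minute on one CPU, and the
package's complete test suite — including five null studies at full design
size — in a few minutes. Unit tests use a miniature 4-joint, 16-specimen
configuration with ~300-channel axes.

## Known limitations

PLS1 with a fixed 0.5 threshold provides no probability calibration and no
multi-class support; no EMSC/MSC or rubberband baseline correction; no
sequential or hierarchical fusion variants (SO-PLS, PO-PLS) or
compression-based fusion; LV selection is non-nested; no permutation
p-values or bootstrap intervals for the accuracies. These are deliberate
scope boundaries, not oversights.
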