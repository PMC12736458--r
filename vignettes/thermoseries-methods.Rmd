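---
title: "Physiological time series from dynamic breast thermography: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physiological time series from dynamic breast thermography: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoseries)
```

## The problem

Dynamic infrared thermography (DIT) records a sequence of skin-temperature
frames while breast tissue rewarms after a controlled cold stress. Malignant
tissue, with its angiogenesis-driven perfusion and elevated metabolism,
rewarms faster and more focally than healthy tissue. `thermoseries`
implements an analysis chain that turns such a 20-frame sequence into a
five-dimensional physiological time series per subject and classifies
cancer versus control with two complementary models: an interval-based Time
Series Forest (TSF) and a stacked LSTM network.

## Forward model

Two closed forms drive everything:

1. **Point-source surface law.** A spherical heat source of intensity $q$
   (W) buried at depth $d$ (m) below the skin raises the surface temperature
   at radial distance $a$ from the point above it to
   $$T(a) = T_e + \frac{q}{4\pi h_0 (d_\mathrm{eff}^2 + a^2)},$$
   with surround temperature $T_e$, heat transfer coefficient
   $h_0 = 8.77\ \mathrm{W\,m^{-2}\,{}^\circ C^{-1}}$, and effective depth
   $d_\mathrm{eff} = d$ (point form, the default) or $d + R$ (finite-radius
   form, available via `use_radius`). The package inverts the point form, so
   a finite-radius profile yields $d + R$ as its depth estimate — an exact
   identity that the test suite asserts.

2. **Exponential rewarming.** After cold stress the tissue temperature
   follows $T(t) = T_\infty - (T_\infty - T_0)e^{-t/\tau}$, a modified
   Newton-cooling law. The recovery constant $\tau$ (s) is the key kinetic
   biomarker: smaller $\tau$ means faster recovery.

`fit_recovery()` estimates $(T_0, T_\infty, \tau)$ by Levenberg–Marquardt
least squares (`minpack.lm::nls.lm`). Initialization is deliberately dumb —
first observation, last observation, a third of the time span — because it
is robust for monotone rewarming curves. On noisy data the $\tau$ direction
can collapse into a degenerate step-function optimum pinned at the lower
bound, so the fitter multi-starts $\tau$ over span
$\times\{1/10, 1/3, 1, 3\}$, discards bound-pinned solutions, and keeps the
lowest residual sum of squares; it never returns a fit worse than its
initialization. Constant series are reported as unidentifiable
($\tau = \mathrm{NA}$) rather than fitted.

## The D-I-R inversion

Given a frame and a region-of-interest (RoI) mask, `frame_descriptors()`
computes the descriptor vector $(T_{max}, T_{mean}, \sigma, q, d)$:

* $T_{max}$: hottest masked pixel (row-major tie-break, documented);
* $T_{mean}$, $\sigma$: mask mean and standard deviation ($n-1$);
* $q, d$: inversion of the surface law from the radial profile around the
  hotspot at the fixed distance $a = 0.0168$ m,
  $$d = a\sqrt{\frac{T(a)-T_e}{T_{max}-T(a)}},\qquad
    q = \frac{4\pi h_0 (T(a)-T_e)(T_{max}-T_e)\,a^2}{T_{max}-T(a)}.$$
  The auxiliary equivalent radius $R = (q/(Q_m A_t))^{1/3}$ with
  $Q_m = 418.6\ \mathrm{W\,m^{-3}}$, $A_t = 1$ is returned but not used as a
  classification feature. $A_t$ is treated as a dimensionless scale: its
  printed unit in the source literature is not a volume, and 1.0 is the only
  self-consistent reading.

Numerical choices that matter:

* **$T(a)$ sampling.** Default is the mean over the one-pixel-wide masked
  annulus $|r - a| \le \mathrm{pitch}/2$, consistent with the radially
  symmetric model; a two-point horizontal "line" mode is offered as the
  literal reading of sampling on each side of the maximum. The annulus
  discretization contributes at most a half-pixel error (about 2% on $d$ at
  a 1 mm pitch).
* **$T_e$ estimation.** How the surround temperature is obtained from data
  is genuinely open; the default is the 10th percentile of masked
  temperatures (a "surround tissue" proxy), with a constant override for
  when $T_e$ is known. Ambient room temperature (20–22 °C) was rejected: it
  yields implausibly large intensities. Because the default estimator is a
  quantile of the same frame, $q$ and $d$ are invariant to adding a constant
  to the frame — a tested property. The quantile proxy is biased relative to
  the true baseline (upward on hotspot-dominated frames, downward on
  heterogeneous ones); this bias is common to both classes and does not
  impair classification, but parameter-recovery oracles in the tests supply
  the known baseline instead.
* **Degenerate frames.** A profile without thermal contrast
  ($T_{max} \le T(a)$ or $T(a) \le T_e$) raises a typed condition; sequence
  extraction carries $q, d, R$ forward from the last valid frame (leading
  gaps fill backward) and flags the frame, so every subject keeps all
  M = 20 frames. $d$ is computed per frame (keeping the tensor
  $M \times V$ with $V = 5$); collapsing to a per-subject median is a
  one-liner on the output table if desired.

## The synthetic cohort

No patient data ship with the package. `generate_cohort()` draws balanced
cohorts of 20-frame sequences (15 s apart, five minutes total) that mimic
the statistical structure the analysis assumes. Each frame is composed of:

* a class-specific exponential rewarming baseline — control
  $(T_0, T_\infty, \tau) = (32.14\ {}^\circ C, 32.63\ {}^\circ C, 57.76\ s)$,
  cancer $(32.69, 33.80, 56.26)$, i.e. the cohort-level fits the package is
  designed to reproduce;
* a hotspot bump following the point-source law — cancer $q = 0.132$ W at
  $d = 0.02$ m, offset from the mask center (asymmetry); control intensity
  near zero ($0.01$ W; hotspots "absent");
* a smooth spatial heterogeneity field: Gaussian-blurred white noise
  (separable blur, $\sigma = 6$ px), centered and scaled per class
  (control 0.90 °C, cancer 1.00 °C, anchored to the spatial-sd range of
  cohort descriptive statistics), drawn once per subject and held fixed
  across frames;
* i.i.d. Gaussian sensor noise (sd 0.05 °C) redrawn every frame.

The hotspot intensity is time-varying,
$q(t) = q\,[0.3 + 0.7(1 - e^{-t/\tau})]$, so the $q(t)$ series is
informative; the latent source dynamics are not specified anywhere, and
tying them to the rewarming factor is the package's own choice. Per-subject
biological variability (shared warmth offset sd 0.25 °C, amplitude sd
0.15 °C, log-$\tau$ sd 0.08, log-$q$ sd 0.15) is added because a cohort
with zero inter-subject variance would make classification trivially
perfect; the values are chosen to be small relative to the between-group
contrasts, which is what the well-separated source cohorts suggest. The
default geometry is a 96 × 96 grid at 1 mm/pixel, so the fixed profile
radius $a = 0.0168$ m spans about 17 pixels and fits inside the elliptical
RoI even at the cancer hotspot offset.

What the phantom deliberately does **not** model: breast anatomy, emissivity
and radiometric camera effects, the cooling phase itself (sequences start at
the post-stress temperature rather than simulating the fan-cooling
criterion), multiple hotspots, and motion. Tests passing on this phantom
therefore show that the pipeline recovers what the forward model planted
and that the classifiers detect the planted group contrast — not clinical
performance on real thermograms.

## Classifiers

**Time Series Forest.** Each of `n_trees` trees samples `k` random
temporal intervals per variable (length uniform on $[\ell_{min}, M]$, then
start uniform; `k = round(sqrt(M))` by default, following the interval-based
ensemble literature), summarizes every interval by (mean, sd, least-squares
slope), and grows a CART-style tree to purity on the resulting $3kV$
features using entropy information gain. Among equal-gain thresholds the
widest margin wins, and an optional secondary comparator
(`margin_tie_break`) extends that margin preference across features —
mirroring the entropy-plus-margin split criterion described for the original
ensemble, whose exact formula is not published. Prediction is majority
vote; the cancer-vote fraction serves as the ROC score; tied votes go to
control (conservative for a screening score). Temporal importance credits
each split's size-weighted impurity decrease to every time index of the
split feature's interval, normalized to unit mass. `tsf_grid_search()`
implements the 3 × 3 grid (100/200/300 trees, $\ell_{min}$ 3/5/7) under
stratified 5-fold CV with ties resolved toward the smaller forest.
Training is single-threaded by design: predictions are a pure function of
(data, config, seed).

**LSTM.** The gating equations
$f_t = \sigma(W_f[h_{t-1},x_t]+b_f)$,
$i_t = \sigma(W_i[h_{t-1},x_t]+b_i)$,
$\tilde C_t = \tanh(W_C[h_{t-1},x_t]+b_C)$,
$C_t = f_t \odot C_{t-1} + i_t \odot \tilde C_t$,
$o_t = \sigma(W_o[h_{t-1},x_t]+b_o)$,
$h_t = o_t \odot \tanh(C_t)$
are implemented twice: a literal per-step reference cell
(`lstm_cell_step()`) and the vectorized batched trainer cell. Their
agreement (to well below 1e-5 over 20-step trajectories with random
weights) plus a finite-difference gradient check of the full network are
the core anti-regression oracles. The classifier stacks LSTM(64) and
LSTM(32), batch-normalizes the final hidden state, applies dropout
(default rate 0.5; the alternative printed rate 0.1 is config-exposed),
then a dense ReLU layer of 16 units and a sigmoid output; binary
cross-entropy is minimized with Adam. Training hyperparameters not stated
anywhere — learning rate 1e-3, batch size 16, up to 200 epochs, early
stopping patience 20 — are conventional defaults and configurable. All
computation is in R; training is exactly reproducible given the seed.

**Fold protocol.** Evaluation uses stratified 5-fold cross-validation. The
LSTM path standardizes features with moments fitted on the training fold
only and carves a stratified 20% of the training fold out as the
early-stopping validation set *before* augmentation, so no augmented copy
of a validation subject is ever trained on. (The sources state both "global"
standardization and fold-wise normalization; the fold-wise, leakage-safe
variant is the default, and a global mode is a trivial pre-pass.)
Augmentation triples the training partition exactly: each sequence
contributes itself, one Gaussian-noise copy (sd 0.05 per feature value),
and one forward time-shift copy (1 or 2 frames, earliest measurement
repeated) — the "3×" is read as 3× total, the composition implied by
listing exactly two augmentation strategies. The TSF path uses the raw
tensor: no standardization (interval statistics are scale-equivariant and
trees are threshold-based) and no augmentation.

**Metrics and comparison.** Accuracy, F1 for the cancer class, and AUC by
the tie-averaged rank (Mann–Whitney) formula; normalized confusion matrices
scale each truth row to rates, so the diagonal is (specificity,
sensitivity). Mean ROC curves are vertically averaged at 101 evenly spaced
FPR points (no recipe is prescribed anywhere; vertical averaging is the
common default). Feature sets FS1–FS4 are compared with the Friedman test
(via `stats::friedman.test`, degenerate all-tied input short-circuited to
$\chi^2 = 0, p = 1$) and pairwise Wilcoxon signed-rank tests computed by
full enumeration of the $2^n$ sign assignments — at $n = 5$ folds the
asymptotic approximation is unreliable and `stats::wilcox.test` abandons
exactness under ties or zero differences, both of which are routine for
fold metrics. Raw p-values are reported without multiple-testing
correction, matching how such comparisons are usually displayed.

## A worked run

```{r, eval = FALSE}
cfg <- phantom_config(n_per_class = 25, seed = 101)
cohort <- generate_cohort(cfg)
tensor <- assemble_tensor(cohort_descriptors(cohort))

cv_tsf <- cross_validate(tensor, tsf_pipeline(n_trees = 100),
                         folds = 5, seed = 1)
cv_lstm <- cross_validate(tensor,
                          lstm_pipeline(lstm_config(max_epochs = 40,
                                                    patience = 10)),
                          folds = 5, seed = 1)
```

On this default synthetic cohort both classifiers reach a mean CV AUC of
at least 0.9 (the acceptance suite asserts exactly this, alongside
label-permutation controls falling in the 0.3–0.7 chance band). Problem
sizes used throughout the tests — cohorts of 16–50 subjects, forests of
15–100 trees, LSTMs trained for tens of epochs — are chosen so the full
suite runs in a couple of minutes while still exercising every code path
at the study's native scale (N = 50, M = 20, V = 5).

## Known limitations

* The phantom's group contrast is generous by construction; real DIT
  cohorts have lower signal-to-noise, segmentation error, and acquisition
  artifacts the generator does not emulate.
* The surround-temperature estimator is a quantile heuristic; absolute
  $q$ and $d$ values inherit its bias even though classification does not.
* The point-source inversion assumes a single dominant hotspot; multi-focal
  disease violates it.
* The LSTM is a compact native implementation: single-threaded, CPU-only,
  sufficient for M = 20 sequences at cohort scale but not meant for large
  imaging workloads.
* Real-data ingestion expects the plain-text temperature-matrix layout;
  adapters for camera-native formats are out of scope.
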