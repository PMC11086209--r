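---
title: "Quantifying surgeon stress and ergonomics from multimodal sensor streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying surgeon stress and ergonomics from multimodal sensor streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surgstress)
```

## The problem

Tele-operated surgical consoles decouple the surgeon from the patient, which
makes the operator's own physiological and ergonomic state newly measurable:
a chest-strap ECG band yields beat-to-beat RR intervals, fiducial markers
glued to the hand controllers yield 6-DoF poses at 10 Hz from an external
RGB-D camera, and a side-view video yields 2D body-landmark tracks. This
package implements a complete, tested pipeline that turns those streams —
plus a six-dimension workload questionnaire (scores 1–20) and manually
recorded task scores — into (i) a per-trial stress estimate, (ii) a
per-trial battery of 25 kinematic, postural, questionnaire and task metrics,
(iii) a significance-tiered correlation report of each metric against the
stress estimate, and (iv) an expert/novice classification experiment driven
by approximate-entropy features.

Because the underlying clinical recordings are not publicly deposited, the
package ships a first-class synthetic cohort generator with *planted*
stress and skill structure. Every pipeline stage is exercised end to end
against it, and the ground truth it records is what the test suite checks
recovery against.

## Stress from heart-rate variability

The stress estimate is the Baevsky Stress Index. RR intervals are first
rounded to 50 ms bins for noise reduction; on the binned histogram,

\[
\mathrm{SI} = \frac{\mathrm{AMo}}{2\,\mathrm{Mo}\,\mathrm{MxDMn}},
\]

where Mo is the modal binned interval (seconds), AMo the mode's share of all
beats (percent), and MxDMn the range between the longest and shortest binned
interval (seconds). Under sympathetic stress the RR histogram concentrates
(AMo up, MxDMn down), so SI rises; with these units healthy resting values
land in the tens to low hundreds, which is the convention implemented here.

Numerical choices, each covered by a test:

* rounding is to the *nearest* multiple of the bin width, with exact
  midpoints rounding away from zero (825 → 850 at 50 ms bins);
* MxDMn is computed on the binned series, consistent with the statistic
  being a histogram functional;
* multimodal ties resolve to the smallest RR value, keeping the statistic
  deterministic;
* a constant (zero-range) series has no defined SI and raises an error
  rather than returning infinity;
* windowed computation uses the half-open window `[t_start, t_end)` and
  requires at least 10 beats — mode and range statistics below that are
  noise.

```{r}
baevsky_si(rr_series(t = 1:4, rr_ms = c(800, 800, 800, 850)))
```

## Hand kinematics from fiducial markers

Marker detections arrive as axis-angle rotation vectors plus translations in
the camera frame. Because the camera is only loosely attached to the
console, every frame is rebased into the frame of a fixed reference marker:
with homogeneous transforms \(H_1\) (reference) and \(H_k\) (hand marker),
the hand pose in the console frame is \(H_1^{-1} H_k\). Rotations come from
the Rodrigues map; the z (depth) component of each translation is replaced
by the RGB-D depth reading where present, which is more accurate than the
size-based estimate. Only the translation is retained — the marker placement
on the controllers makes orientation uninformative by design.

Per hand and trial the pipeline reports: the 3D spatial standard deviation
\(\sqrt{\sigma_x^2+\sigma_y^2+\sigma_z^2}\) (population variances); the
bounding-box diagonal as the single "range" scalar (per-axis extents are
also returned); path length; average speed; and mean jerk norm. Jerk is
estimated by the third-order *central* finite difference
\((x_{i+2}-2x_{i+1}+2x_{i-1}-x_{i-2})/(2\,\Delta t^3)\) on a regular 10 Hz
grid after linear interpolation; that stencil needs five grid samples, so
five is the documented minimum (a four-sample trajectory has no interior
stencil point). Detection gaps longer than 0.5 s are never interpolated
across: segments are differenced independently and combined weighted by
duration. Bimanuality is summarized by dominant/non-dominant ratios of path
length and range; the dominant hand defaults to the right (all study
subjects were right-handed) and is overridable.

## Posture metrics

From the 33-point landmark numbering only the right shoulder (id 12) and
right elbow (id 14) are reliably visible from a camera on the subject's
right. The primary metric per landmark is the time-averaged absolute
vertical velocity, mean |Δy| / mean Δt — the "_vy" reading of vertical
displacement; the peak-to-peak vertical range is exported alongside as a
secondary descriptor since the underlying study definition is not
recoverable. Absolute differences make the metric independent of whether
image y grows up or down. Posture video runs on its own clock, so each trial
carries a manually determined offset applied before analysis.

## Stream synchronization and the correlation report

Hand trajectories and posture tracks are resampled by linear interpolation
onto a shared 10 Hz grid over the task window (a 1 µs tolerance absorbs
timestamp round-trip jitter at file boundaries); RR intervals stay an event
series consumed per window. Each trial contributes one row: SI plus 25
metrics in a fixed battery order. A metric whose computation fails on a
trial (constant heart rate, missing stream, zero ratio denominator) is
flagged missing — never zero-filled — and excluded pairwise from that
metric's correlation, with the per-metric pair count reported.

Correlations are Pearson coefficients over all trials pooled, with two-sided
p-values from the exact t transform \(t = r\sqrt{(n-2)/(1-r^2)}\). Tiers
follow the study's bands: p < 0.05 strong; 0.05 ≤ p ≤ 0.08 weak ("possible,
worth a larger dataset"); above, none. Both boundaries fall in the weak
band, reading "between 0.05 and 0.08" as a closed interval. Two-sided
p-values are the conservative choice given the study states signed
hypotheses but not sidedness. No multiple-testing correction is applied,
matching the reported analysis; the report is exploratory by construction.

## Skill classification

Each questionnaire dimension is binarized at the mean of its responses:
below the mean → 0 (expert class), above → 1 (novice class), exactly at the
mean → 0 (the published rule covers only strict inequalities; ties going to
the expert class keeps the rule total and deterministic).

Time-series channels are reduced to approximate entropy,
\(\mathrm{ApEn}(m, r) = \Phi^m(r)-\Phi^{m+1}(r)\), with Chebyshev distance
and self-matches included, at the standard convention m = 2,
r = 0.2·sd(channel); a constant channel short-circuits to 0. The feature
vector has eleven entries: instantaneous heart rate (60000/RR resampled to
the grid), right- and left-hand x, y, z, and shoulder/elbow x, y. The raw RR
series versus derived heart rate is not determinable from the study text;
the heart-rate reading is implemented because it lives on the same time
grid as the other channels. The ApEn core is compiled (Rcpp) and is checked
in the tests against a brute-force O(N²) template-counting oracle and
against an independent CRAN implementation.

Four classifiers are tuned by exhaustive grid search under LOOCV and
stratified k-fold CV:

* **Decision tree** (implemented in the package, since no installed tree
  exposes these semantics): split criterion gini/entropy, max depth
  None/1–10, per-split feature subsampling None/sqrt/log2 plus eleven
  evenly spaced fractions from 0.1 to 1 (the enumerated grid totals 616
  combinations), splitter best/random (random draws one uniform threshold
  per candidate feature).
* **k-NN** (implemented here): neighbours 1..(smallest training fold),
  uniform/inverse-distance weights, euclidean/manhattan/minkowski metrics.
* **SVM** via `e1071`/libsvm: the nine C values, four kernels and eleven
  gamma values of the protocol (396 combinations); `scale`/`auto` gammas
  use the feature-count and total-variance conventions.
* **Logistic regression** via `glmnet` with `lambda = 1/(C·n)` and
  unstandardized features, pairing each solver only with the penalties it
  admits (liblinear/saga: l1+l2; newton-cg/lbfgs/sag: l2), 63 combinations.
  The solver axis is enumeration-only: every listed solver converges to the
  same penalized optimum, so combinations sharing a penalty and C score
  identically — the axis is kept so the search space matches the protocol.

A parameter combination is scored by the mean over folds of out-of-fold
accuracy (for LOOCV this equals pooled accuracy); whether the study reported
mean-CV or best-fold accuracy is ambiguous, so `aggregate = "best_fold"` is
available behind a flag. Fold assignment is stratified and seeded (default
7919), ties go to the earlier grid row, and degenerate single-class training
folds fall back to the majority class, so reports are byte-reproducible.

## The synthetic cohort

The generator emulates the study conditions: three groups (novices,
residents, board-eligible surgeons) of five subjects, four tasks each,
truncated to 58 trials; two-minute tasks sampled at 10 Hz. Each trial draws
a latent stress level s ~ Uniform(0, 1), independent of group skill.

* **RR intervals**: Gaussian with mean 900 − 150·s ms and sd 90·(1 − 0.7·s)
  ms, truncated at 300 ms — higher stress means faster, more rigid heart
  rate, hence higher SI by construction. This is a histogram-level
  simplification, not a physiological beat model: the downstream statistic
  only consumes the histogram.
* **Hands**: mean-reverting AR(1) walks. The left hand is a fixed-shape
  walk multiplied by the planted envelope 0.05 + 0.06·s m (bounding-box
  diagonal), so every left-hand metric is exactly scale-covariant in the
  envelope — all planted positive. The right hand has a fixed envelope and
  per-step volatility falling 35 % across the stress range, so its path
  length, speed and jerk are planted negative while its spread metrics are
  only mechanically (weakly) coupled. The free constants were calibrated
  once by simulation so that at s = 0.5 the dominant/non-dominant path
  ratio averages 1.7 and the bounding-box ratio 6.2, the study's cohort
  anchors; frozen values sit at the top of `R/cohort.R`.
* **Camera**: the planted trajectories are emitted as raw marker
  observations composed through a wobbling camera pose (AR(1) perturbations
  of 0.02 rad / 5 mm), so reconstruction must genuinely rebase; the emitted
  translation z carries 4 mm noise while the depth channel is exact, making
  depth substitution material to exact recovery.
* **Posture**: baseline + slow drift + oscillation with amplitude
  0.01 + 0.04·s (normalized image units) and 2 mm detection noise; the
  posture clock is shifted by a recorded random offset the pipeline must
  undo.
* **Questionnaire**: physical fatigue ≈ 1 + 12·s and distractions ≈
  1 + 10·s with discretized Gaussian noise clipped to 1..20 (planted
  positive); the other four dimensions are driven by skill or pure noise
  (null with respect to stress). Manual error counts are Poisson with rates
  decreasing in skill — null with respect to stress by design, since skill
  and s are independent.

`planted_links()` records, per metric, the planted sign and a strength
class: `strong` (calibrated, expected detectable at n = 58), `induced`
(mechanical couplings such as the two ratio metrics and the right-hand
spread metrics, direction recorded but strength not calibrated), `null`.
The acceptance tests check sign recovery and detection power on the strong
set, and the ≈5 % strong-tier false-positive rate on the null set, across
200 seeded cohorts.

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: ECG morphology and ectopic beats, biomechanically
coupled arm motion (the two hands are independent walks), marker dropout
and occlusion bursts, pose-estimation failure modes (clothing, head
position), learning effects across a subject's four tasks, and
within-subject correlation (trials are generated independently, which makes
the pooled-correlation design assumption exactly true here and only
approximately true in reality).

## Problem sizes in the shipped checks

The test-suite and acceptance-script runs use the study-scale defaults —
58 trials of 120 s at 10 Hz — for cohort-level checks, with 200 seeded
cohort replicates for recovery rates and 10 000 replicates for tier
calibration. The end-to-end classification demonstrations tune over trimmed
grids (a documented subset per classifier) while full-grid behaviour is
exercised separately on smaller feature sets; cardinalities of the full
grids are asserted exactly.

## Known limitations

* The Pearson p-value is exact only under bivariate normality; SI is
  right-skewed, so tier boundaries on real data inherit that
  approximation. The tier calibration test checks the null rate, not power
  under skew.
* Jerk on interpolated grids is biased low within interpolation gaps;
  segments shorter than five grid samples contribute nothing.
* The logistic-regression solver axis cannot reproduce solver-specific
  non-convergence artefacts of other implementations.
* `binarize_target` thresholds at the within-sample mean, so class balance
  — and the chance rate that accuracies should be compared against —
  varies per question and cohort.
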