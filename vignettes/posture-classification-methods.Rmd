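---
title: "Classifying work postures from an instrumented insole and helmet IMU"
author: "PostureSense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying work postures from an instrumented insole and helmet IMU}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PostureSense)
```

## The problem

Prolonged or inadequate working postures are a major risk factor for
work-related musculoskeletal disorders. PostureSense implements a
wearable-sensor methodology for telling adequate from inadequate postures
automatically, using two cheap, non-intrusive devices: an instrumented
insole with four force sensors under the (dominant) right foot, and a
helmet-mounted accelerometer. Six work situations are distinguished,
covering three workstation tasks each performed adequately and
inadequately: static load carriage (situations 1 and 2), dynamic handling
movements (3 and 4), and static unloaded standing (5 and 6). Static trials
last 20 s, dynamic trials 15 s.

## Center of pressure

The center of pressure (COP) is the point location of the vertical ground
reaction under the foot. With $n$ force sensors at insole coordinates
$(X_i, Y_i)$ (mm; $X$ mediolateral, $Y$ anteroposterior, origin at the
lower-left corner of the insole's bounding rectangle) reading pressures
$P_i$, the COP is the pressure-weighted barycenter

$$X_{COP} = \frac{\sum_i X_i P_i}{\sum_i P_i}, \qquad
  Y_{COP} = \frac{\sum_i Y_i P_i}{\sum_i P_i}.$$

This is a ratio, so raw (uncalibrated) sensor units are acceptable: any
positive rescaling of the pressures cancels. With non-negative pressures
the COP cannot leave the convex hull of the sensor positions. The COP path
in the plane is the *statokinesigram*; its per-axis time series are the
*stabilograms*.

Sampling rates are configurable (default 100 Hz for both streams, a typical
posturography/IMU rate). Velocities are forward differences scaled by the
sampling rate, with no smoothing: smoothing changes the velocity statistics
and therefore must be an explicit, separate choice, not a hidden default.
The COP is likewise not filtered or detrended before feature extraction.

## The direct feature bank (60 features)

`extractDirect()` computes, per trial:

* **Stabilogram statistics (12)** — mean, max, standard deviation,
  variance, RMS and kurtosis of $X_{COP}$ and $Y_{COP}$.
* **Velocity statistics (18)** — the same six statistics of the resultant
  speed $V$ and of the signed components $V_X$, $V_Y$. Components are kept
  signed (their maxima differ from the resultant's), which is why the bank
  lists $V$, $V_X$ and $V_Y$ separately.
* **Statokinesigram features (8)** — total path length `lg_tot`, mean and
  SD of segment lengths, first-to-last-point distance `dist_prdr`,
  per-axis amplitudes `Am_X`/`Am_Y` (max − min), the 90% ellipse area
  `surf_ellip`, and the length-over-surface ratio `lfs`.
* **Frequency features (4)** — mean and median frequency of each
  mean-removed stabilogram.
* **Head-acceleration statistics (18)** — the six statistics per axis of
  the helmet accelerometer.

The registry order is fixed (per-axis blocks of mean, max, std, var, rms,
kurtosis; then statokinesigram, frequency and acceleration blocks) so
feature indices are stable across runs.

Numerical conventions, chosen once and asserted by tests:

* **Kurtosis** uses the Pearson convention (a normal signal scores 3, not
  0); a zero-variance signal has undefined kurtosis and is reported as 0
  with a warning.
* **90% ellipse**: the Gaussian prediction ellipse, the standard
  posturography construction. From the eigenvalues $\lambda_1, \lambda_2$
  of the sample covariance, the semi-axes are
  $\sqrt{\chi^2_2(0.90)\,\lambda_i}$ and the area
  $\pi\,\chi^2_2(0.90)\sqrt{\lambda_1 \lambda_2}$ (with
  $\chi^2_2(0.90) \approx 4.605$). For a large isotropic Gaussian cloud
  with unit variance this is $\approx 14.46$ and empirically contains 90%
  of the samples.
* **`lfs` for a degenerate (zero-area) trajectory** is defined as 0 with a
  warning rather than propagating an infinity into the selection stage;
  such trajectories only arise synthetically.
* **Spectra** are single periodograms of the mean-removed, unwindowed
  signal; resolution is one DFT bin ($f_s/T$ Hz). A Welch estimator would
  trade bin resolution for variance; the simple periodogram keeps the
  estimator transparent and the tests exact (a pure tone lands in its bin;
  white noise has mean frequency $f_s/4$).
* **Amplitude** (`Am_X`, `Am_Y`) is interpreted as the per-axis range.

## The graphic feature bank

The graphic approach turns the trajectory itself into features: the insole
area is fixed to the 43 × 134 mm rectangle bounding all COP positions and
discretized into a binary occupancy matrix — a cell is 1 iff the COP
visited it at least once. Cells are emitted as features named
`g_r<row>_c<col>`. Occupancy is strictly binary; dwell-time (gray-level)
images are deliberately out of scope.

Seven resolutions are supported. The published cell sizes determine the
(rows × cols) factorizations uniquely over 43 × 134 mm:

| cells | rows × cols | cell size (mm) |
|------:|------------:|---------------:|
| 420   | 12 × 35     | 3.58 × 3.83    |
| 574   | 14 × 41     | 3.07 × 3.27    |
| 768   | 16 × 48     | 2.69 × 2.79    |
| 990   | 18 × 55     | 2.39 × 2.44    |
| 1220  | 20 × 61     | 2.15 × 2.20    |
| 1564  | 23 × 68     | 1.87 × 1.97    |
| 2187  | 27 × 81     | 1.59 × 1.65    |

(The 420-cell mediolateral size is sometimes quoted as 3.50 mm, which no
integer row count over 43 mm can produce; 43/12 = 3.58 is the consistent
value.) Cells are half-open, closed at the far edge; a sample exactly on a
boundary belongs to the higher-index cell. Samples up to 0.5 mm outside
the bounds are clamped (the bounds are defined as the min/max over all
measurements, so real data sits inside by construction); anything further
out is an error. The default working resolution is 990, the
best-performing graphic resolution.

## Hybrid feature selection

Dimensionality is reduced in two stages (`hybridSelect()`):

1. **Filter.** Five classifier-independent scores per feature: Fisher
   criterion $F = (\mu_2-\mu_1)^2/(\sigma_1^2+\sigma_2^2)$, absolute Welch
   two-sample $t$, absolute between-class Pearson correlation $|R|$
   (pairing trials by index; class sizes are equal by design), one-way
   ANOVA $F$, and ReliefF (multi-class, $k = 10$ neighbors, Manhattan
   distance on range-normalized features, every trial an anchor). The
   two-class scores are extended to six classes by averaging over all 15
   unordered class pairs. Each test's score vector is min-max normalized
   to $[0,1]$ (infinite scores from vanishing denominators are first
   capped one unit above the finite maximum) and the *aggregate* score is
   the per-feature mean of the five. Both single-test rankings (the
   default variant is the two-sample $t$) and the aggregate ranking are
   available; the top 20 features are kept.

   Design notes: $|t|$ and $|R|$ are used because ranking needs the
   magnitude of separation, not its sign. The Welch denominator is the
   standard $\sigma^2/n$ form. Whether Pearson relevance should be $|R|$
   or $1-|R|$ is genuinely ambiguous as a class-similarity measure; $|R|$
   is implemented, and the Pearson-only variant is indeed the weakest
   filter, consistent with either reading. Min-max normalization is the
   simplest transform satisfying "scores between 0 and 1".

2. **Wrapper.** Sequential forward selection (SFS) around the classifier:
   starting from an empty set, repeatedly add the candidate whose addition
   maximizes the mean CV recognition rate, until all 20 candidates are
   ordered. The evaluator is one repetition of stratified 10-fold CV with
   a fold assignment fixed by the seed (the 10-repetition protocol is
   reserved for final reporting; one repetition keeps the
   $20+19+\dots+1 = 210$ evaluations affordable). Ties go to the earlier
   candidate. The retained subset is the shortest prefix whose accuracy is
   within 0.001 of the trace maximum — a stopping rule that keeps few
   features when the trace saturates early.

## The classifier

A single-hidden-layer perceptron: $i$ inputs (the selected features), 12
hidden units with hyperbolic-tangent activation, and a softmax output over
the 6 classes. The loss is the mean cross-entropy
$E = -\tfrac{1}{l}\sum_j \sum_i T_{ij} \ln S_{ij}$ (perfect one-hot
predictions score 0; uniform predictions score $\ln 6 \approx 1.792$),
plus a small $L_2$ weight penalty ($10^{-4}$) for conditioning. Training
uses Polak–Ribière conjugate gradients (base R `optim(method = "CG",
type = 2)`) from small uniform random initial weights drawn from a private
seeded RNG stream, so training is exactly reproducible. Inputs are z-score
standardized with parameters fitted on the training fold only (tanh units
need standardized inputs; fitting on the training fold keeps the
evaluation leakage-free). Argmax ties resolve to the lowest class index.

Evaluation (`evaluateCv()`) is stratified 10-fold cross-validation
repeated 10 times; the performance measure is the mean recognition rate
over the 100 fold rates. Stratification is necessary with only 20 trials
per class. Default training length in the pipeline is 100 conjugate
gradient iterations, which saturates accuracy on this problem size at a
fraction of the cost of full convergence.

## The synthetic benchmark

No participant recordings are distributed, so `generateCorpus()` produces
a seeded synthetic corpus with the statistical structure the features are
designed to detect — 20 trials per situation by default, 120 in all:

* **Static situations** follow a mean-reverting AR(1) COP (pull-back
  coefficient 0.95) around a situation-specific center, with stationary
  dispersion a few mm for adequate postures (1: 2.0 mm, 5: 1.5 mm) and
  markedly more for inadequate ones (2: 6.0 mm, 6: 5.0 mm). Centers
  differ by situation: forward trunk lean and load carriage shift the COP
  anteriorly.
* **Dynamic situations** superimpose a sinusoidal sweep across much of the
  insole (3: ±35 mm anteroposterior at 0.30 Hz; 4: ±50 mm at 0.45 Hz with
  a wider mediolateral component).
* **Head accelerations** are situation means plus Gaussian noise; the
  static means are approximately $(X,Y) = (2,0), (2,2), (1,0), (2,0)$
  m/s² for situations 1, 2, 5, 6, with the vertical axis dominated by
  gravity (9.81 m/s²); dynamic situations add an oscillation synchronized
  with the sweep.
* **Trial-level random effects** — lognormal jitter on dispersion, noise
  and sweep amplitude, ±2.5 mm center jitter, ±0.35 m/s² acceleration-mean
  jitter — emulate an operator's natural trial-to-trial variability.
  Without them every class is separable by a single feature and the
  benchmark says nothing about the pipeline; with them single features
  peak near 75% CV accuracy and multi-feature selection is actually
  exercised.

Pressures are produced by allocating a total load (≈700 N body weight,
plus 9 × 9.81 N in the load-carrying situations — cosmetic, since the
barycenter is scale-invariant) across the four sensors with bilinear
weights of the target COP relative to the sensor rectangle, so the
barycenter formula recovers the simulated path exactly; non-rectangular
layouts fall back to non-negative least squares. This makes
`computeCop()` exactly invertible for testing (round-trip error ≪ 0.1 mm
RMS).

What the generator does *not* emulate: real plantar pressure
distributions, foot anatomy, sensor nonlinearity/saturation, drift, or
genuinely nonstationary movement strategies. Passing benchmarks therefore
demonstrate that the pipeline recovers the *designed* class structure at
realistic noise levels, not field performance on human data.

## Problem sizes and costs

The shipped benchmark scale — 120 trials at 100 Hz, hybrid selection over
20 candidates with a 1×10-fold SFS evaluator at 100 CG iterations,
10×10-fold final evaluation — runs in a few minutes on one CPU core. Unit
tests use a 36-trial corpus at 50 Hz. On the default benchmark
(seed 1) the hybrid-selected direct features reach a mean recognition rate
above 90%, and adding the hybrid-selected resolution-990 graphic features
keeps the combined rate above 95%; the graphic features alone classify
markedly worse (near 80%), as expected from binary occupancy alone.

## Known limitations

* The generator's class contrasts are stylized; effect sizes are stated
  defaults, not estimates from human data.
* ReliefF is $O(\text{trials}^2 \cdot \text{features})$; at the 990-cell
  resolution this is still cheap, but the aggregate filter recomputes all
  five tests even when a single-test variant is requested.
* The Pearson filter pairs trials by within-class index, so it depends on
  trial ordering; the other four tests are permutation-invariant.
* A single right-foot insole is assumed; between-feet total-COP analysis
  is explicitly out of scope.
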