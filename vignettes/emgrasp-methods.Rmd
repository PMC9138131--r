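---
title: "Methods: simulating and analyzing the limb-position effect in grasp classification"
author: "emgrasp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing the limb-position effect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
decisions behind `emgrasp`, in the spirit of a methods section: what each
stage assumes, which knobs matter, and what the synthetic testbed can and
cannot tell you about real recordings.

## The scientific setting

In myoelectric control, a pattern classifier maps windowed surface-EMG
features to an intended grasp. Classifiers trained with the arm in one
position degrade when the limb moves, because muscles adjust contractile
strength to stabilize the limb: feature clusters for the same grasp shift
with position, and clusters from different grasps start to overlap. The
package reproduces this regime end to end with synthetic data: five grasp
classes (sphere, cylinder, keycard, eraser, pen) at nine object placement
positions arranged in three azimuths (-45°, 0°, +45°) by three distances,
with six EMG channels (1024 Hz) and a six-channel IMU (60 Hz).

## The signal generator

Each 2 s trial is generated independently from a counter-derived substream
of one dataset seed, so trial generation is order-independent and
bit-reproducible.

**EMG.** Channel `ch` under grasp `g` is an AR(2)-filtered Gaussian process.
The pole radius and angle (spectral shape, driving ZC/SSC/AR features) and
the amplitude (driving MAV/WL/RMS features) are deterministic functions of
`(g, ch)` scaled by `classSeparation`. Grasp identity must live in *both*
amplitude and spectrum: the feature set contains both kinds of descriptors,
and amplitude-only signatures would leave the AR features uninformative.
Limb position multiplies each channel by `1 + positionEffect * delta[p, ch]`
with `delta` a per-subject standard-normal draw — the simplest mechanism
consistent with position-dependent contractile adjustment. White measurement
noise (`noiseSd`, default 0.05) is added on top.

**IMU.** The accelerometer reads the gravity unit vector rotated by the
position's azimuth and a distance-dependent tilt (10° per distance rank)
plus noise, which makes the ACC channel means position-informative by
construction; the gyroscope is zero-mean noise whose variance grows with the
position index.

**Default effect scales.** The literature quantifies the regime only through
the separability index of the raw MAV/SSC feature space (single-digit SI
when positions are pooled, roughly 4–16 within single positions). The
defaults `classSeparation = 1`, `positionEffect = 0.35` were fixed once so
the generator lands in that regime — measured on the 12-dimensional
all-channel MAV+SSC block at two repetitions per cell: pooled SI 3.4,
per-position SI 7.6–11.1 — and are not revisited per experiment. ("MAV/SSC
scatter" is ambiguous about channel choice; we read it as the all-channel
feature block.)

**What the generator does not emulate:** motor-unit physiology, electrode
lift-off or sweat artifacts, reach/return phases (only the analyzed 2 s
grasp-and-lift phase is produced), inter-day electrode shift, or fatigue
drift. Passing tests on this testbed demonstrate that the *pipeline*
(features → projection → classifier → metrics) behaves as designed under a
position-shift mechanism; they do not certify error rates on real subjects.

## Conditioning and windowing

EMG is band-passed 20–450 Hz (5th-order Butterworth) and notch-filtered at
50 Hz. The notch is a standard audio-EQ biquad with Q = 30 (≈1.7 Hz
bandwidth); no published design was available to copy. Both filters are
applied forward-backward (zero-phase) so that features stay time-aligned
with labels — a causal implementation would shift energy ~ms-scale without
changing any conclusion here. Filtering happens once per recording, before
segmentation, so window contents cannot depend on segmentation order. The
IMU moving average defaults to 5 samples (~83 ms at 60 Hz).

Windows are 150 ms with 50 ms increments. Sample counts use nearest-sample
rounding, `N = round(0.150 * rate)`: 154 EMG and 9 IMU samples per window at
the default rates (the EMG/IMU spans then agree to <1 ms). A 2 s trial
yields 38 windows.

## Features and normalization

The 66-vector is, per EMG channel: MAV, ZC, WL, SSC, AR1..AR6; then the six
IMU RMS values. Three conventions worth stating:

* WL is the plain sum of absolute successive differences (the conventional
  definition), not an average.
* ZC and SSC use strict inequalities with no amplitude deadband; products
  equal to zero do not count.
* The AR model is the standard `u_i = sum_{p=1..6} a_p u_{i-p} + e_i`,
  estimated by Burg's method, which is stable on 154-sample windows. A
  printed lag range starting at 0 would make the model degenerate, so lags
  1..6 are used. Constant windows return zero coefficients and are flagged
  in the dataset metadata rather than erroring out mid-pipeline.

Normalization maps each feature by `x -> 2 (x - min)/(max - min) - 1` using
*training* extrema only; test values may leave [-1, 1] (no clipping — the
mapping is affine, and clipping would discard information the classifiers
can use). Constant features map to 0.

## Projections

All four methods reduce to k = 4 dimensions (classes minus one).

**PCA / LDA.** Standard eigen-decompositions; LDA uses the unnormalized
scatter matrices and regularizes `Sw` by `1e-9 * trace(Sw)/m` on the
diagonal so degenerate synthetic inputs stay invertible. Eigenvector signs
are fixed deterministically (largest-magnitude component positive).

**SRELM.** Hidden parameters `(a_i, b_i) ~ U(-1, 1)` are drawn once under a
seed and *persisted*: transforming new data reuses the training-stage
parameters (fresh draws would make the fitted output weights meaningless; an
equivalent reading is regeneration under the same seed). The activation is
`g(d) = 1/(1 + e^d)` exactly as specified upstream — it lacks the customary
negative sign, but the hidden draws are sign-symmetric, so the function
class is identical. The response matrix `Z` maps labels to an n x c
indicator matrix, deflates the all-ones direction, and keeps c - 1
orthonormal columns (the spectral-regression construction); the output
weights solve the ridge problem in closed form. The study's operating point
(L = 1000 hidden nodes, alpha = 1) is the default; `srelmGridSearch()`
scans alpha in 1..10 and L in 50..1500 by cross-validated error with ties
resolved toward smaller L, then smaller alpha.

**t-SNE.** Implemented from first principles: per-point bandwidths by
bisection to the target perplexity (tolerance 1e-5, ≤50 iterations),
symmetrized joint probabilities, Student-t low-dimensional kernel, gradient
descent with momentum 0.5→0.8 (switch at iteration 250), learning rate 200,
adaptive gains, early exaggeration x4 for 100 of 1000 iterations, N(0, 1e-4)
initialization — the original publication's defaults, since no settings are
prescribed upstream. t-SNE has no out-of-sample map, so train and test rows
are embedded **jointly (transductively) with labels withheld** and split
back by row index. Consequently, in cross-validation the t-SNE path
normalizes over all rows and embeds once per dataset; this is the one
deliberate exception to the train-only-fitting rule, and it is inherent to
using a transductive method inside CV rather than a leak we could remove.
Whether the original study refit per fold is unknowable from its text; the
transductive choice is documented as ours.

## Classifiers

Operating points: KNN k = 3; SVMs at cost = 1, gamma = 1 (polynomial degree
3, coef0 = 0, one-vs-one multiclass, inputs standardized by the SVM
backend); NN 4-14-5 with tan-sigmoid hidden layer and linear outputs.
Decisions the upstream description leaves open, fixed here:

* NB is Gaussian naive Bayes, computed in log space with a variance floor —
  projected grasp clusters can have per-feature standard deviations of order
  1e-3, where naive density products underflow.
* KNN ties (possible with k = 3 and 5 classes) resolve to the candidate
  class with the smallest mean neighbor distance.
* The NN trains by full-batch gradient descent, momentum 0.9, learning rate
  0.01, 500 epochs, mean-squared error on one-hot targets, argmax readout,
  seeded uniform initialization. Its inputs are z-scored with training-fold
  statistics: projection outputs differ by orders of magnitude in scale
  (t-SNE coordinates O(10), SRELM outputs O(0.01)), and a fixed learning
  rate needs a common scale.

Cross-validation is five-fold over a seeded shuffle of all windows of one
subject (fold sizes within one of each other). Normalizer, projection and
classifier are fitted inside each training fold (t-SNE excepted, above).

## Cluster metrics

SI, MSA and RI follow the definitions in the README. Two conventions: the
semi-principal axes in MSA are the *square roots* of the covariance
eigenvalues (an ellipsoid's semi-axis length), and near-singular covariances
receive a `1e-9 * trace/k` diagonal ridge before inversion. SI is affine
invariant, so it can be compared across projection methods with arbitrary
output scalings.

## The two experiments

**Projection x classifier grid.** All 4 x 7 pairings per subject under
five-fold CV; per-fold projections are computed once and shared by the seven
classifiers. SI/MSA are reported from a projection fitted on all of the
subject's normalized data (the per-fold numbers differ only by sampling).

**Training-position reduction.** The schedule hard-codes the nested
best-position subsets (P5; P5,P9; P1,P5,P9; …; P1–P9) rather than
re-searching them. Windows are split 80/20 *within every position*; the 80%
side of the scheduled positions trains, and the held-out 20% of **all nine
positions** tests. (Using all windows of all positions as the test set would
place training rows inside it; the within-position holdout keeps the
comparison leak-free while preserving the intent — training coverage varies,
testing coverage is always complete.) Reported per subset: percent error,
SI of the projected training data, and RI between the projected training
data and the all-position test data.

## Problem sizes and runtime

The default experiment scale in the tests and the acceptance script is one
subject, two repetitions per (grasp, position) cell, and every eighth window
of each trial (5 windows/trial, 450 windows in total). These sizes are the
package's choice for a desk-scale testbed: the qualitative findings under
study — supervised projections separate better than unsupervised; classifier
choice matters least under SRELM; error and RI fall as training positions
are added — are stable at this size across seeds, while a full-resolution
run (5 reps, all 38 windows, 8550 windows) changes only the sharpness of the
same orderings. t-SNE dominates the runtime (its joint-probability and
gradient computations are O(n²) per iteration), which is why the embedding
is computed once per dataset and reused across folds and classifiers.

## Known limitations

* Synthetic EMG is a stationary AR(2) process per trial; real grasp EMG is
  nonstationary within the grasp-and-lift phase.
* The position effect is a static multiplicative gain; real limb-position
  effects also alter spectral content and electrode-muscle geometry.
* Absolute error rates and metric magnitudes on synthetic data are not
  comparable to values measured on human subjects; only orderings and trends
  are meaningful.
* t-SNE results depend on the transductive protocol; a deployment scenario
  (classify new windows in real time) would need a parametric surrogate.
* The HDF5 container mentioned alongside the CSV layout in some workflows is
  out of scope; delimited text is the supported interchange format.
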