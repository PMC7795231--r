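---
title: "Sleep posture monitoring from chest-labeled wrist accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep posture monitoring from chest-labeled wrist accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnipose)
library(dplyr)
```

## The problem and the approach

Gross sleep posture — supine, prone, left or right lateral — matters
clinically (positional apnea, pressure-injury prevention, medication side
effects), but the standard way to obtain it is a chest-worn sensor that is
uncomfortable to wear every night. somnipose implements a two-phase
alternative built around *automatic labeling*:

1. **Training phase.** The wearer uses two tri-axial accelerometers at 60 Hz
   (range −2..2 G): one strapped tightly to the chest, one on the wrist.
   The chest sensor's orientation is a direct, deterministic readout of
   trunk posture, so it supplies the labels; the wrist sensor supplies the
   features. No human annotation is involved.
2. **Monitoring phase.** Only the wrist sensor is worn. A classifier trained
   on the joined data predicts posture from the wrist features alone.

## The chest labeler

Four deterministic steps convert the chest stream into one posture label
per second.

**Calibration.** The sensor is a flat disc; its rotation about the
chest-normal axis is arbitrary. While the wearer stands or sits straight,
gravity should load a single axis, so we estimate the mounting angle as
$\theta = \operatorname{atan2}(\bar a_y, \bar a_x)$ over the upright
reference interval and rotate every sample's $(x, y)$ pair by $-\theta$:

$$\begin{pmatrix} x' \\ y' \end{pmatrix} =
  \begin{pmatrix} \cos\theta & \sin\theta \\ -\sin\theta & \cos\theta \end{pmatrix}
  \begin{pmatrix} x \\ y \end{pmatrix}.$$

After calibration the upright gravity vector lies exactly on $X'$
($y'$-residual of the reference mean is zero to machine precision), and the
rotation preserves each record's XY norm. The calibration uses the
arithmetic mean of the reference interval — the same statistic as the
feature windows, and robust to per-sample noise. Only $(x, y)$ rotate; $Z$
is the chest-normal axis and is left untouched. The reference interval
defaults to the first 5 s of the recording (configurable); the rotation is
planar, so no gyroscope or magnetometer is needed.

**Noise removal.** Early-stage hardware occasionally emits spurious records
with near-zero values. Within each one-second window we take the sample
variance of the vector magnitudes as an adaptive threshold and drop the
records whose magnitude falls below it. A quiet window of genuine ~1 G
samples has variance around $10^{-4}$–$10^{-3}$, far below 1 G, so nothing
is removed; one near-zero glitch inflates the variance to roughly
$1/n_w$ G² (about 0.017 at 60 Hz), which sits cleanly between the glitch
(< 0.01 G) and the real data (~1 G). Whether the threshold applies to
magnitudes (default) or per axis is a configuration switch, since either
reading is defensible; magnitudes are axis-symmetric, which fits an
artifact defined by "extremely small values".

**Windowing.** Non-overlapping, half-open windows
$[k w, (k+1) w)$ with $w = 1000$ ms; per-axis arithmetic means. Half-open
boundaries make the window partition exact (a record at exactly $t = 1000$
belongs to window 2); a trailing partial window is kept if it holds at
least one record, and windows left empty by cleaning are skipped.

**Decision rules.** The dominant axis is the largest absolute mean. $X'$
dominant means standing; otherwise $Y'$ positive/negative is left/right
lateral and $Z$ positive/negative is supine/prone. The labels are
scale-invariant (only direction matters), so no gravity normalisation is
required. Exact ties have measure zero; they are broken by the fixed
priority $X' > Y' > Z$ and reported.

## Wrist features and the design matrix

The wrist stream is segmented with the same half-open one-second frames and
each frame is reduced to its per-axis means $(\mu_x, \mu_y, \mu_z)$ — the
full feature set; no variance, frequency-domain or orientation-angle
features are used. Both sensors stream to the same phone and so share the
session clock; wrist frames and chest windows are joined on their index,
rows present on only one side are dropped and counted. `Stand` windows stay
in the training set by default (they are part of the label vocabulary), and
`keep_stand = FALSE` gives a sleep-only model.

## Classifiers

**One-against-all SVM.** One binary soft-margin RBF SVM per class, trained
on the $\pm 1$ relabeling of that class against the rest. The dual problem

$$\max_\lambda \sum_i \lambda_i -
  \tfrac12 \sum_{i,j} \lambda_i \lambda_j \hat Y_i \hat Y_j K(X_i, X_j),
  \qquad \textstyle\sum_i \lambda_i \hat Y_i = 0,\; 0 \le \lambda_i \le C,$$

with $K(a,b) = e^{-\gamma\|a-b\|^2}$, is solved by sequential minimal
optimization (delegated to libsvm via e1071; trained models are checked
against the box and equality constraints). The decision rule, kernel
expansion $\operatorname{sign}(\sum_i \lambda_i \hat Y_i K(X_i, Z) + b)$,
and the voting are implemented natively: a "+" outcome adds one vote to the
model's own class, a "−" outcome adds one vote to *every other* class, and
the class with the most votes wins. Under this literal rule an all-minus
outcome gives every class $k-1$ votes; that tie — and any other — is broken
toward the earliest class in the fixed order Stand, Supine, RightLateral,
LeftLateral, Prone, with a warning. A `method = "margin"` option replaces
voting with the argmax of the raw decision values for users who prefer the
common continuous variant. A decision value of exactly zero classifies as
"+" (a deterministic convention for a measure-zero event); values within
$10^{-12}$ of zero are treated as zero to keep the convention meaningful in
floating point.

Defaults are $C = 1$ and $\gamma = 1/(3 \cdot \operatorname{var}(X))$ (the
common "scale" heuristic); no published values exist for this pipeline, so
both are exposed everywhere.

**Random forest.** Bootstrap-resampled trees with random feature subsets
(`mtry = 1` of the 3 features), Gini splits, majority vote across trees
with the same fixed-order tie-break. The tree learner is ranger; the vote
tally is native so the tie behaviour is exactly the documented one. The
tree count is selected by `select_tree_count()`: one seeded 2/3–1/3
train/validation split, forests for every count 1–50, argmax of validation
accuracy with ties going to the smallest count (the cheapest adequate
model; on well-separated data a single tree often suffices, so small
selections are expected). `repeated_trials()` repeats the full
split/train/test cycle (100 trials by default, trial $k$ seeded
`base_seed + k`) and summarises the accuracy spread with the mean, the
25th/75th percentiles and Tukey 1.5·IQR outliers. Trials use a fixed tree
count (default 25) rather than re-running selection inside each trial,
which would multiply the cost fifty-fold without changing the spread
picture.

## The session simulator

`simulate_session()` generates paired chest/wrist streams with known
ground truth so every stage is testable without recorded subjects:

* **Chest**: the posture's canonical gravity direction, rotated in the
  X–Y plane by a mount angle (drawn uniformly unless fixed) — exactly the
  miscalibration the chest pipeline must undo — plus i.i.d. Gaussian noise
  (default sd 0.05 G).
* **Wrist**: a posture-conditioned unit orientation, redrawn each second
  around the posture's mean with a per-posture angular dispersion (the
  wrist is not rigidly coupled to the trunk), plus the same Gaussian noise.
* **Artifacts**: with probability `glitch_rate` per sample, the record is
  replaced by a random direction scaled below 0.01 G — the "extremely
  small values" the cleaning stage targets.
* **Truth**: the majority posture of each complete window (ties toward the
  earlier bout). Output is clipped to the ±2 G sensor range.

Every session starts with an upright segment so calibration is always
possible. Two profiles fix the study conditions:

* `separable`: the five wrist orientation means sit on coordinate axes
  (pairwise ≥ 90°), dispersion 0.1, no overlap — comfortably learnable;
  feature-space class means are several standard deviations apart.
* `confusable`: Prone's wrist mean is mixed 0.6 of the way toward
  RightLateral's and its dispersion raised to 0.35 (vs 0.15), and Prone
  receives half the dwell of the other lying postures. This encodes the
  two ingredients of real prone confusion — the right wrist can sit almost
  identically in prone and right-lateral positions, and the better-
  represented class wins the contested region — so prone's per-class
  accuracy lands strictly lowest in the large majority of seeds.

What the simulator does *not* model: limb micro-movements and posture
transitions inside a bout, respiration/heartbeat components, sensor drift,
clock skew between the two devices, and attachment slip. Passing tests on
simulated sessions therefore demonstrate that the pipeline's geometry,
cleaning, joining and learning machinery are correct under the stated
generative assumptions — not that any particular accuracy will be achieved
on recorded subjects.

## Numerical and design choices

* Windows/frames: half-open, 0-based in time, 1-based in index; partial
  trailing windows kept.
* Sample variance (denominator $n-1$) is used for the noise threshold; at
  60 samples per window the distinction from the population variance is
  immaterial to which records are removed.
* Tie-breaks everywhere are deterministic and documented (axis priority,
  earliest class in canonical order), so runs are exactly reproducible
  from their seeds; the forest is trained single-threaded for the same
  reason.
* Verification sizes: the SVM implementation is checked against an exact
  active-set solver of the dual on all 351 two-point datasets and seeded
  samples of three- and four-point datasets drawn from a 3×3×3 lattice,
  comparing decision signs at all 27 lattice probes; probes where the
  exact decision value is within 5·10⁻³ of zero are not sign-compared,
  since the SMO termination tolerance leaves the sign at the numerical
  boundary undefined. Recovery checks use 510-window sessions, 5 seeds for
  the separable profile and 10 for the confusable one; repeated-trial
  summaries use 100 trials.

## A worked run

```{r, eval = FALSE}
session <- simulate_session(default_config("separable", seed = 42))

reference <- dplyr::filter(session$chest, timestamp_ms < 5000)
rotation <- compute_calibration(reference)
labels <- label_stream(session$chest, rotation)

dataset <- session$wrist |>
  frame_means() |>
  build_dataset(labels)

n_trees <- select_tree_count(dataset, seed = 42)
model <- train_rf(dataset, n_trees = n_trees, seed = 42)

cm <- confusion_matrix(dataset$posture, predict_rf(model, dataset))
overall_accuracy(cm)
autoplot(cm)
```

## Known limitations

* The wrist–posture relationship is assumed stationary within a subject;
  the cross-subject protocol (`cross_subject_eval()`) measures, but does
  not correct, distribution shift between wearers.
* The labeler trusts the chest sensor completely; a loose chest strap
  produces wrong labels that propagate silently into training.
* Features are means only; postures distinguished by movement dynamics
  rather than static wrist orientation are outside the feature set's reach.
* The raw-dialect parser implements the single documented line form; other
  brace arrangements found in the wild should be added as new dialects
  rather than by loosening this one.
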