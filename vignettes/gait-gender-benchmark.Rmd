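---
title: "Synthetic point-light walkers and the sequence-vs-static gait classification benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic point-light walkers and the sequence-vs-static gait classification benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gaitlab)
```

## The problem this package addresses

Human observers can judge the gender of a walker from a handful of moving
dots placed at body joints, and they do so best when dynamic cues — the
timing and amplitude of lateral sway — are visible, rather than static
structural cues such as stature. The same contrast can be posed to machine
learners: a recurrent sequence model (an LSTM) reads joint trajectories in
temporal order, while margin- and entropy-based static models (SVMs, small
decision forests) only ever see order-invariant summaries. `gaitlab`
implements that comparison end to end as a reproducible benchmark:
a parametric generator of 20-joint, 24 fps skeletal walking data with
controllable gender cues; the shared preprocessing stack; two static
featurizations; the three classifier families; subject-wise
cross-validated exposure-duration sweeps; and the t/F statistics used to
summarize them.

A synthetic generator stands in for motion-capture data because
benchmark-grade skeletal gait recordings with gender labels are rarely
distributable (the study population this design mirrors — 41 adults, 26
male and 15 female, walking 6 one-minute treadmill sessions at 24 frames
per second — was never deposited). The generator's role is not
biomechanical fidelity; it is to plant *known, separable* gender cues so
that every downstream claim ("sequence models exploit dynamics", "static
clinical metrics carry no gender signal here") can be tested against
ground truth.

## The kinematic model

Each walker is a kinematic chain over the canonical 20 joints (head, neck,
mid-spine, pelvis, and left/right shoulder, elbow, wrist, hand, hip, knee,
ankle, foot), driven at the stride fundamental `f = 1 / gait_cycle_period`:

* pelvis lateral sway `hip_sway_amp * sin(2*pi*f*t)`, vertical bounce at
  `2f`, and a shoulder girdle counter-sway of amplitude
  `shoulder_sway_amp` phase-offset by `pi`;
* legs in antiphase, with the hip-to-ankle line angle following a
  *time-warped* cosine whose descending (stance) limb occupies
  `duty_factor` of the cycle and whose ascending (swing) limb the
  remainder — heel strike at phase 0, toe-off at phase `duty_factor`;
* knee flexion as a double bump per cycle (a stance bump of 30% of
  `knee_flexion_max`, then a swing bump peaking at `knee_flexion_max`),
  realized by two-link inverse kinematics about the hip–ankle line. This
  construction is deliberate: it guarantees the ankle's anterior extrema
  fall exactly at the gait events, so event detection and stride
  estimation have exact closed-form ground truth
  (`ground_truth_metrics()`);
* arms antiphase to their ipsilateral legs with a constant elbow bend;
* additive i.i.d. Gaussian jitter per coordinate (`noise_sd`, default
  5 mm — the scale of consumer depth-sensor noise);
* a treadmill convention: the pelvis has exactly zero anterior drift.

The hip-angle amplitude is `asin(stride_length / (4 * leg_length))`, which
makes the per-stride peak-to-peak anterior excursion of the ankle relative
to the pelvis exactly `stride_length / 2` — the identity the clinical
extractor inverts.

### Where the gender signal lives

`effect_config()` draws per-subject parameters from gender-conditional
truncated Gaussians. Two cue channels are planted:

* **dynamic**: the shoulder/hip sway-amplitude ratio, male mean 1.3 vs
  female 0.7 (SD 0.25). This is carried entirely by motion and survives
  height normalization.
* **structural**: stature (sampled from the study population's
  gender-conditional means and SDs, truncated to each gender's stated
  range — the printed female mean lies below the printed female minimum
  and both SDs are implausibly large for stature, so truncation is what
  keeps the draws anatomically sensible) and the shoulder:hip width ratio
  (1.15 vs 0.95).

`cue = "dynamic"` pools the structural distributions so *only* sway
carries gender; `cue = "height_only"` plants the signal solely in the cue
height normalization removes. These switches exist because the benchmark's
logic — sequence models should beat static ones when the signal is
dynamic, and everything should collapse to chance when the only cue is
stature — is only testable when the experimenter controls the cue.

Gait-cycle period defaults to 1.6 s (75 steps/min), reading a 0.4 s
exposure as a quarter of a *full* cycle; descriptions equating two full
cycles with 2.7 s circulate in the perception literature and are noted,
not adopted. Other defaults: stride 1.2 m (SD 0.12), duty factor 0.62,
vertical bounce 3 cm, arm swing 0.35 rad, peak swing knee flexion 60 deg.
Weight and age are sampled as metadata only and never drive kinematics.

## Preprocessing

All experiments share one stack, each stage frozen from training data
where it has state:

* `height_normalize()`: one scalar rescale to unit median head-to-foot
  extent plus pelvis centering. Removes stature, preserves proportions
  and sway ratios.
* `smooth_moving_average()` (5 frames, shrinking centered window at the
  edges) and `differentiate()` (forward difference times fps) build the
  velocity representations. Differentiation is length-preserving (final
  difference repeated) so velocity and position windows pair one-to-one.
* `project_coronal()` drops the anterior-posterior axis: the
  40-dimensional frame vector of the walker seen head-on.
* `window_split()`: windows are defined in *frames*, `10k` for
  `k = 1..10`, non-overlapping by default. Stated second labels
  ("0.4–3.8 s") are nominal at 24 fps; frames are the ground truth unit
  because 10 frames at 24 fps is 0.417 s and an arithmetically even
  sweep in seconds does not exist at this frame rate.
* `fit_scaler()` / `apply_scaler()`: per-feature z-score, then min–max to
  `[-1, 1]` using training extrema (that order; both transforms are
  stated by the protocol, their order is not). Held-out values may fall
  outside `[-1, 1]` and are not clipped; zero-variance features map to 0
  with a warning. Statistics are computed per feature over all training
  windows and frames — per-window or per-sequence granularities would
  erase the between-subject amplitude differences the cue lives in.

## Featurizations and models

The static route summarizes a window by four first-order statistics
(min, max, mean, population SD — population rather than sample SD, fixed
for reproducibility) of each dimension, giving 240 values for 3D input;
or by 12 clinical spatiotemporal metrics per session: stride length,
cadence, walking speed, step length, single- and double-support
fractions, per-leg stance:swing ratios, and per-leg time-averaged knee
flexion in stance and swing. The listed clinical battery names eleven
unambiguous quantities; step length is the derived twelfth. Gait events
come from the foot-relative-to-pelvis anterior extremum method (heel
strike at maxima, toe-off at the following minimum, peaks found on
5-frame-smoothed signals with a minimum separation of 0.4 estimated
cycles, the cycle estimated from the dominant autocorrelation lag of
pelvis sway) — the standard marker-based choice when no force plates
exist.

The sequence route feeds windows, in temporal order, to a single-layer
LSTM (128 hidden units by default; input, forget, output gates and tanh
candidate; no peepholes; forget-gate bias initialized at 1; weights
`N(0, 0.1)` — the initialization SD is a free choice, as only "zero-mean
Gaussian" is pinned down). The final hidden state is ReLU-activated into
an affine head with 2 logits trained by softmax cross-entropy (the
one-hot-regression reading of the same architecture is rejected in favor
of the standard softmax likelihood) with Adam at learning rate 0.001,
batches of 50, 100 epochs, no early stopping, no dropout, no schedule.
The cell, backpropagation through time, and Adam are implemented in this
package in base R with batched matrix algebra, and are verified by
finite-difference gradient checks and a closed-form parameter-count test
(`4(H(D+H)+H) + 2H + 2`).

SVMs use libsvm (e1071) with linear, RBF (gamma 0.99) and sigmoid
kernels, `C = 1` (unstated upstream, configurable). The forest is 10
trees with at most 3 features per split and a minimum of 2 samples to
split (randomForest; its Gini impurity stands in for entropy — the two
impurity measures are monotone-similar and choose near-identical
thresholds on continuous features). SVM "probabilities" are a logistic
transform of the signed decision value: a monotone surrogate, so the
reported label always equals the margin-side class; the forest's are
tree-vote fractions.

## Experiment harness

`subject_kfold()` partitions *walkers*, gender-stratified, into
near-equal folds (41 subjects at k = 10 gives nine folds of 4 and one of
5); windows from one subject never straddle train and test, which is the
guard against identity leakage. `run_experiment()` executes the factorial
(family x representation x window length x replicate x fold); replicates
re-seed fold assignment and model initialization, and reported numbers
are means with standard errors over replicates. Prediction counts are
reported exactly as realized (a round "250 predictions per duration"
cannot arise from 246 sessions, so no such number is forced). Stimulus
clips for point-light display work reproduce the display geometry: 20
dots of 5 px radius on a 1920x1080 canvas, the walker box 2.5 x 4 degrees
inside a 6 x 8 degree field, with psychophysics exposures restricted to
{0.4, 1.5, 2.5, 3.8} s.

The statistics module implements the two tests the benchmark reports:
a two-tailed one-sample t against chance over replicate accuracies, and a
two-tailed variance-ratio F between two cohorts of accuracies, `F =
s_A^2 / s_B^2` on `(n_A - 1, n_B - 1)` df — the construction whose
degrees of freedom match cohort sizes minus one, e.g. (9, 20) for 10
model replicates against 21 observers. A mean-comparison reading of the
same comparisons (Welch/ANOVA) is deliberately not substituted; both
implementations are cross-checked against `t.test()`/`var.test()` to
1e-10 in the suite. p-values are reported exactly, never binned, and no
multiplicity correction is applied (none is part of the protocol being
mirrored).

## What the tests do and do not show

The test and acceptance suites run at desk scale: cohorts of 10–20
walkers, sessions of 20 s, 2–3 folds, 3–10 replicates, LSTMs of 16–32
hidden units trained for 15–25 epochs. These sizes are the package's own
choice of smallest-cohort-that-still-separates; the defaults of every
function remain the full study conditions (41 walkers, 6 x 60 s, 128
units, 100 epochs). Checks performed:

* null calibration — with subject-level label permutation every family
  sits within 3 SE of 50% at every window length. The SE uses the
  replicate spread with a binomial floor of `sqrt(0.25 / (n_subjects *
  n_replicates))`: under subject-wise cross-validation the predictions
  within one subject are strongly dependent, so the effective sample
  size for a label-uninformed classifier is subjects, not windows;
* planted-effect recovery — with a dynamic-only cue, the velocity LSTM
  beats the position LSTM at longer windows (70 frames; differentiation
  amplifies the i.i.d. jitter, so the velocity advantage needs enough
  frames for the recurrent model to average the noise out), both beat
  chance, and clinical-metric models do not (the clinical battery
  deliberately contains no sway quantity);
* duration trend — LSTM accuracy does not fall from 10-frame to
  100-frame windows, while static-model accuracy has no significant
  slope over window length;
* metric recovery — cadence, speed and stride length from zero-noise
  trajectories match closed forms within 5% (median over 50 subjects);
* dimensional equivalence — 2D and 3D LSTMs are statistically
  indistinguishable when the planted cue is coronal.

Passing these shows the pipeline is internally coherent and that the
models behave as their information access dictates *on data whose cues
are known*. It does not show that real Kinect recordings are this
separable: real gait has inter-stride variability, soft-tissue and
tracking artifacts, occlusions, and correlated (not i.i.d.) sensor
noise, none of which the generator emulates. Absolute accuracies on
synthetic cohorts are therefore not comparable to accuracies on recorded
data; only the *orderings and invariances* above are the reproducible
claims.

## Numerical and degenerate-input choices

Truncated-normal sampling uses the inverse-CDF construction (exact, no
rejection loops). Event detection refuses sequences with no periodic
pelvis sway (variance or autocorrelation below threshold) rather than
returning empty events; `window_split()` on a too-short sequence warns
and returns an empty list rather than erroring, so sweeps degrade
gracefully. Zero-variance accuracy vectors in the t-test produce the
sign-convention limit (p = 0 off chance, p = 1 at chance) with an
explicit flag; a zero denominator variance in the F-test flags an
infinite statistic. The softmax is max-shifted; probabilities are floored
at 1e-12 inside the loss. Forest vote ties break toward the first class
level, fixed by sorted level order.

## Known limitations

The generator's gait is stylized: sinusoidal drives plus a stance/swing
time-warp, rigid segments, no double-bounce asymmetry, no arm-trunk
coupling, no inter-stride variability. Height normalization uses the
median frame extent, so extreme crouching would bias it. The LSTM is
CPU-bound R; at full study scale (128 units, 100 epochs, 10 x 10
fold-replicate sweeps over 10 durations) it is a long run — the harness
is factored so cells can be distributed, but no parallel backend is
bundled. The clinical-metric battery is one defensible reading of a
partially ambiguous list; alternates (e.g. splitting support fractions
differently) are a configuration away but not implemented as options.
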