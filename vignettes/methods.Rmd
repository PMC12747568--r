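---
title: "Detecting alcohol-impaired gait: models, pipeline and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting alcohol-impaired gait: models, pipeline and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Alcohol intoxication degrades postural control: trunk sway increases,
cadence slows, stride timing becomes irregular and the crisp push-off of a
confident step flattens out. A waist-mounted smartphone accelerometer sees
all of this as changes in the triaxial acceleration signal — mediolateral
(X), vertical (Y) and anteroposterior (Z). `intoxgait` implements a complete
pipeline that turns such recordings into a per-window binary intoxication
decision: subject-wise preprocessing, a handcrafted gait-feature bank for
classical baselines, and a multichannel Conv1D–BiLSTM–attention deep
classifier with interpretability tooling.

Real alcohol-administration datasets are not publicly available, so the
package ships a synthetic gait generator that is a first-class, tested
module: every claim the test suite makes about the pipeline is made against
data whose ground truth is known by construction.

# The synthetic gait generator

Each axis is a sum of harmonics of the step frequency with axis-specific
amplitudes (vertical largest, as for a real torso), per-subject random
cadence and amplitude offsets (log-normal, ~10%), white sensor noise, and
optional sparse high-magnitude excursions at Poisson times emulating falls
or abrupt turns. All randomness derives from one seed via stage- and
subject-hashed child seeds, so cohorts are bit-reproducible and the sober
and intoxicated renditions of a subject share the same underlying gait.

Intoxication acts through four mechanisms, chosen to mirror the clinical
phenomenology:

* `sway_multiplier` (default 1.5) inflates the mediolateral amplitude
  (postural sway);
* `cadence_slowdown` (default 0.92) slows the step frequency;
* `phase_jitter_sd` (default 0.15 rad) adds per-stride phase noise
  (irregular stride timing);
* `vertical_damping` (default 0.80) attenuates the *above-fundamental*
  harmonics of the vertical axis — cautious, flat-footed steps lose the
  sharp push-off transient, which lives in the higher harmonics.

The last point is a deliberate interaction with the preprocessing: the
pipeline z-scores each axis per subject, so any purely multiplicative
amplitude change (such as the sway factor on X) is normalized away before
the classifier ever sees it. A harmonic-*ratio* change reshapes the
waveform itself and survives normalization. This makes the vertical channel
the dominant class-informative channel by construction, which in turn makes
the channel-masking ablation a meaningful test: masking Y must hurt, masking
a noise-only Z must not. Units are nominal g; the z-scoring removes scale,
so only ratios matter.

Defaults the generator states as study conditions: 210 Hz sampling, sober
cadence 1.8 Hz, sober BAC exactly 0, intoxicated BAC uniform on
0.08–0.20 g/dL, and an intoxicated-subject fraction of 0.2513 reproducing
the roughly 75/25 sober/intoxicated sample imbalance of controlled
alcohol-administration studies. A session is labelled intoxicated whenever
its BAC exceeds a configurable threshold whose default is 0 — sober means
BAC exactly zero.

What the generator does *not* emulate: device heterogeneity, orientation
drift, free-living activity mixtures, fatigue or injury confounds, and
inter-stride correlation structure beyond simple phase jitter. Passing
tests on this cohort therefore demonstrate that the pipeline and model are
implemented correctly and can learn the kind of spectral-shape signal
intoxication produces — not that any particular accuracy transfers to real
subjects.

# Preprocessing

The cleaning chain runs per subject, strictly inside each data split, in
this order: stratified subject-wise split → per-subject z-score → Isolation
Forest outlier removal → zero-phase low-pass filter → sliding-window
segmentation → (training set only) random oversampling.

* **Split.** Whole subjects are assigned to train/validation/test with
  target sample fractions 0.70/0.10/0.20. Within each class, subjects are
  taken largest-first (ties shuffled under the seed) and assigned greedily
  to the split with the largest sample-count deficit; stratifying the
  greedy pass by class keeps each split's class ratio close to the cohort's
  while the deficit rule keeps the sizes on target. A repair step re-homes
  one subject if a positive-fraction split would otherwise be empty. The
  assignment is the leakage guard: no subject's windows ever cross a split.
* **Z-scoring** uses the population standard deviation (the definitional
  form of the standardization formula); a zero-variance axis maps to zeros
  with a warning rather than dividing by zero.
* **Isolation Forest.** 100 trees, subsample 256, uniformly drawn split
  attribute and value, depth limit `ceiling(log2(256))`; anomaly score
  `2^(-E(h)/c(n))` with the exact harmonic-sum normalizer. Scoring is
  applied to the raw `(ax, ay, az)` sample rows of one subject, before
  windowing, and exactly the top 5% (the contamination default) are
  dropped; the series closes up and the subsequent low-pass smooths the
  small discontinuities. Window-level scoring was rejected because the
  pipeline removes outliers before segmentation.
* **Low-pass filter.** Third-order Butterworth, 20 Hz cutoff, discretized
  by the bilinear transform (`signal::butter`) and applied forward and
  backward. The forward–backward application is implemented in the package
  with odd-reflection edge padding (up to 300 samples) so that the IIR
  start-up transients decay inside the padding; the net result is zero
  phase and a squared single-pass magnitude response — amplitude 0.5 at the
  cutoff.
* **Windows.** Length 1024 (4.88 s at 210 Hz) with 50% overlap; stride is
  `round(size * (1 - overlap))`, exact for the 50% case. Windows inherit
  the recording's label; sessions are single-condition so no tie-breaking
  is ever needed in practice.
* **Oversampling.** Minority windows are duplicated uniformly at random
  (with replacement) until the training classes balance 1:1. Validation
  and test sets are never oversampled.

# The multichannel hybrid classifier

Each axis is processed by its own column: two Conv1D layers (117 and 175
filters, kernel 6, ReLU, 'same' padding) extract short-term stride
features; a BiLSTM (85 units per direction, returning sequences) models
longer-range temporal structure; an attention stage re-weights the
sequence; global average pooling collapses it to a channel embedding. The
three embeddings are concatenated and passed through Dense(129, ReLU) →
dropout → Dense(188, ReLU) → dropout → Dense(1, sigmoid). Loss is binary
cross-entropy (probabilities clipped at 1e-7); the optimizer is Adam at
learning rate 0.00024227083179696293; dropout rate is 0.696581562334145.
These values are the reported outcome of a Bayesian hyperparameter search
for the full-scale model; the package takes them as given and does not
re-tune them.

The layer order — convolution, then BiLSTM, then attention — follows the
architecture's explicit stage list; where prose summaries elsewhere order
the stages differently, the explicit list wins.

No R deep-learning framework is involved: forward and backward passes are
written in the package (R matrix algebra, with the LSTM recursion and the
batched self-attention kernels in RcppArmadillo). Correctness rests on
finite-difference gradient checks that cover every attention variant and
every ablation at a miniature scale; the checks nudge all parameters off
zero first because zero-initialized biases put ReLU pre-activations exactly
on the kink, where a two-sided difference quotient and a subgradient
legitimately disagree.

## Attention variants

Five selectable per-channel attention stages, all mapping a `T x d`
sequence to a `T x d` sequence:

* **self** (default): learned `Wq/Wk/Wv` projections, scaled dot-product,
  row softmax. A projection-free form (`Q = K = V = X`) is also
  implemented and selectable, since both appear under the same name in the
  literature this package follows.
* **mha**: `h = 4` parallel heads. The published formulation leaves the
  head count unstated and the natural `d/h` head width is not an integer
  at either the full width (170) or the test scale (42), so heads have
  width `floor(d/h)` and a final projection maps `h * floor(d/h)` back to
  `d` — this works at any width while preserving the concatenate-and-
  reproject structure.
* **cross**: each channel's queries attend over the feature-wise
  concatenation of the *other two* channels (keys and values), symmetric
  across channels.
* **temporal**: a scalar score per timestep against a query vector (the
  final BiLSTM hidden state), softmax over time. The output sequence is
  the weighted input scaled by `T`, so the subsequent average pooling
  yields exactly the classical context vector `sum_t alpha_t h_t`; the
  weights have shape `T`.
* **channel**: squeeze-and-excitation — global average over time, a
  two-layer bottleneck (reduction 4), sigmoid gates scaling each feature.

## Ablation switches

`build_model(config, ablation =)` removes exactly one component:
`attention` (identity stage), `bidirectionality` (forward-only LSTM, half
width), `cnn` (raw inputs feed the BiLSTM), `lstm` (attention operates on
conv features). `component_ablation()` trains the full model plus all four
ablations on bit-identical window sets under one seed.

## Training

Minibatch Adam (batch 64), seeded shuffling and dropout, up to 50 epochs
(30 within cross-validation), early stopping on validation loss (patience
5, best weights restored) and learning-rate halving on plateau (patience
3). Patience values and batch size are conventional defaults; the
published description names the mechanisms but not their constants.
Inference disables dropout and is bit-deterministic.

# Evaluation and interpretability

Metrics are accuracy, precision, recall, specificity, F1 and trapezoid
AUC over the full ROC sweep (cross-checked against pROC in the tests), at
a default decision threshold of 0.5 (unstated in the source; 0.5 is the
neutral choice). Undefined ratios report 0 with a flag. Subject-level
k-fold cross-validation partitions subjects into class-balanced folds; a
10% subject-disjoint validation share is carved from each fold's training
subjects for early stopping, and all preprocessing statistics stay inside
the fold.

Attention interpretability collapses each `T x T` attention matrix to a
per-timestep vector by averaging over query rows (the source plots a
T-vector without stating the reduction; row-averaging preserves the
row-stochastic normalization), averages channels and sampled windows per
class (10 per class by default), and smooths with a Gaussian kernel
(sigma 10 timesteps, reflect padding, unit mass — the smoothing operator is
doubly stochastic, so the timeline mean is preserved). Because the
per-window vectors are normalized, the profile's overall level is pinned at
`1/T`; the information is in its *shape* across the gait cycle, which the
quartile phase table summarizes (per-phase class means, their difference,
and the percentage difference relative to sober).

Channel ablation masks one input channel with zeros — which, after
per-subject z-scoring, equals the subject mean — re-evaluates the trained
model, and reports the AUC and accuracy drops plus each channel's drop
relative to the largest (the convention that matches the published
relative-importance column).

# Desk-scale study sizes

The tests and the acceptance script run everything at a reduced scale
chosen as the package's own desk-scale study conditions: windows of 256
samples (1.22 s), all layer widths at 25% of the full model (29/44 conv
filters, 21 LSTM units, 32/47 dense units), cohorts of roughly 60 subjects
with 8-second walks, and at most 10 training epochs. The scaled
configuration uses a learning rate of 2e-3 and dropout 0.3 — values sized
a priori to the smaller parameter count and short epoch budget, not
carried over from the full-scale optimum, whose tiny learning rate and
very high dropout are tuned for millions of windows and 50 epochs. The
structural contracts (sequence lengths, width ratios, gradient flow) are
scale-invariant, which is what the miniature configurations are for.

The learning smoke test uses a cohort whose class signal lives only in the
vertical harmonic ratio (`vertical_damping = 0.25`, no cadence or phase
effects, Z amplitude zero), so that (a) a logistic fit on the handcrafted
feature bank certifies separability before any deep model is trained, and
(b) channel masking has a known ground truth. A seemingly simpler design —
inflating the mediolateral amplitude and keying separability to the
X-channel variance — does not survive this pipeline: per-subject z-scoring
normalizes every axis to unit variance, so amplitude- or variance-based
class signals never reach any classifier. Separability is therefore keyed
to the surviving vertical-shape signal; the oracle logic (a classical fit
must succeed before the deep model is asked to) is unchanged.

# Known limitations

* The synthetic cohort is far easier than real data; reported accuracies
  on it are implementation checks, not clinical estimates.
* The Isolation Forest closes up the series after dropping samples, which
  slightly compresses time; at 5% contamination the effect on the spectrum
  is negligible after low-pass filtering, but extreme contamination values
  would distort cadence estimates.
* Training is CPU-bound R/C++; the full 1024-sample, full-width
  configuration is provided and correct but sized for hours, not minutes.
* The channel-gate attention variant has no per-timestep weights, so the
  attention-profile tooling rejects it rather than inventing a timeline.
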