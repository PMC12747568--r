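# intoxgait

Detecting alcohol-impaired gait from waist-mounted smartphone
accelerometry.

Alcohol intoxication inflates postural sway, slows cadence, makes stride
timing irregular and flattens the vertical push-off of each step. A
triaxial accelerometer worn at the waist records all of this as changes in
the mediolateral (X), vertical (Y) and anteroposterior (Z) acceleration
signals, which makes passive, non-invasive impairment screening possible —
no breathalyzer hardware, just the phone already in the holster.

`intoxgait` implements the full analysis stack for this problem:

* **Synthetic gait simulator** — seedable, per-subject periodic gait with
  class-dependent perturbations (sway inflation, cadence slowdown,
  stride-phase jitter, vertical push-off damping), sensor noise, sparse
  outlier events and a configurable ~75/25 sober/intoxicated imbalance.
  The study data this field works with are not public; the simulator is a
  first-class, tested module that provides ground truth by construction.
* **Subject-wise preprocessing** — stratified subject-disjoint 70/10/20
  splitting, per-subject z-scoring (`z = (x - mu)/sigma`, population
  sigma), Isolation Forest outlier removal (score `s(x,n) =
  2^(-E(h(x))/c(n))`, contamination 0.05), zero-phase third-order
  Butterworth low-pass at 20 Hz, sliding windows of 1024 samples (4.88 s
  at 210 Hz, 50% overlap), and training-set-only random oversampling to a
  1:1 class ratio.
* **Handcrafted gait features** — the 30-feature bank used by classical
  baselines (extrema, moments, band power, spectral entropy/bandwidth,
  sway volume, signal magnitude area, ...) plus plug-in mutual-information
  feature selection `I(X;Y) = sum p(x,y) log[p(x,y)/(p(x)p(y))]`.
* **Multichannel hybrid classifier** — per-axis columns of
  Conv1D(117) → Conv1D(175) → BiLSTM(85, sequences) → attention → global
  average pooling, concatenated into Dense(129) → Dense(188) → sigmoid;
  binary cross-entropy, Adam, dropout 0.6966, early stopping and
  LR-on-plateau. Five attention variants (self, multi-head, cross,
  temporal, channel) and four single-component ablation builders. The
  network, its backpropagation and the optimizer are implemented in the
  package (R + RcppArmadillo) and verified by finite-difference gradient
  checks.
* **Evaluation & interpretability** — trapezoid-AUC ROC metrics,
  subject-level five-fold cross-validation, class-mean attention profiles
  with Gaussian smoothing, gait-phase quartile tables, and
  channel-masking ablation.

## Worked example

Simulate a cohort whose intoxicated subjects lose the second (push-off)
harmonic of the vertical axis — the kind of waveform-shape change that
survives per-subject z-scoring — then run the pipeline at desk scale and
train the scaled model (widths at 25%, 256-sample windows):

```r
library(intoxgait)

sim <- simulation_params(duration_s = 8, cadence_slowdown = 1,
                         phase_jitter_sd = 0, sway_multiplier = 1,
                         vertical_damping = 0.25,
                         harmonic_amplitudes = list(x = c("1" = 0.18),
                                                    y = c("1" = 0.45, "2" = 0.30),
                                                    z = c("1" = 0)),
                         noise_sd = 0.03, outlier_rate = 0, seed = 1)
recs <- simulate_cohort(n_subjects = 32, intox_subject_fraction = 0.25, sim)

pp <- preprocess_cohort(recs, split_spec(seed = 1),
                        filter_spec(), iforest_spec(),
                        window_size = 256, seed = 1)
pp$train
#> <window_set> N=374 T=256 overlap=0.50 | sober=187 intoxicated=187 | 23 subjects

model <- train_model(build_model(scaled_model_config(seed = 1, batch_size = 16)),
                     pp$train, pp$validation, epochs = 10)
classification_metrics(pp$test$labels, predict_model(model, pp$test))
#> <metrics_report> acc=1.0000 auc=1.0000 f1=1.0000 prec=1.0000 rec=1.0000 spec=1.0000 (t=0.50)

channel_ablation(model, pp$test)
#>   channel         axis delta_auc delta_acc relative
#> 1       X      lateral     0.000     0.000        0
#> 2       Y     vertical     0.484     0.167        1
#> 3       Z longitudinal     0.000     0.000        0
```

The training set line shows the pipeline's output: 374 windows after
subject-disjoint splitting and train-only oversampling to a 1:1 class
ratio. The metrics line reads: every held-out test window (from subjects
the model never saw) is classified correctly on this strongly separable
cohort. The channel-ablation table shows what the model relies on: zeroing
the vertical axis costs 17 accuracy points and 0.48 of AUC (relative
importance 1.00), while the lateral and longitudinal channels — which
carry no class signal here — are free to remove. That is exactly the
hierarchy the generator built into the data. With the default, subtler
impairment parameters the desk-scale model is not expected to reach these
numbers; see the vignette for what desk-scale results do and do not show.

The same stages are scriptable from a shell via the thin CLI:

```sh
Rscript inst/cli/gaitpipe.R simulate --seed 1 --out out/
Rscript inst/cli/gaitpipe.R cv --seed 1 --out out/
```

See `vignettes/methods.Rmd` for the model, its assumptions, every tunable
parameter, and the reasoning behind the design choices.

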