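---
title: "Methods: recurrence-plot imaging and convolutional classification of fetal heart rate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recurrence-plot imaging and convolutional classification of fetal heart rate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the method it implements: what
each stage assumes, which knobs matter, what the synthetic generator does and
does not emulate, and where genuinely open design choices were settled.

## The problem

Intrapartum cardiotocography records the fetal heart rate (FHR, beats per
minute, sampled at 4 Hz) during labour. Fetal hypoxia — oxygen deficiency,
objectively indicated by umbilical-artery pH below 7.15 at delivery — leaves
signatures in the FHR: suppressed beat-to-beat (short-term) variability,
fewer accelerations, more decelerations. Visual interpretation is notoriously
inconsistent between obstetricians, which motivates automated screening.

The pipeline here classifies a single FHR segment as `normal` or
`pathological` in five stages:

1. **Preprocessing** — rule-based removal of dropouts, spikes and
   physiologically impossible values (`preprocess_fhr()`).
2. **Phase-space embedding** — the scalar series u becomes points
   x_k = (u_k, u_{k+tau}, ..., u_{k+(m-1)tau}), k = 1..N, N = L − (m−1)tau
   (`embed_delay()`).
3. **Recurrence plot** — the binary N×N matrix
   R_ij = Theta(eps_i − ||x_i − x_j||), with Theta strictly positive
   (Theta(0) = 0) and eps_i the Euclidean distance to the i-th point's k-th
   nearest neighbour, rendered as a 64×64 intensity image
   (`signal_to_rp()`).
4. **Augmentation** — one image per (m, tau, k) grid cell; the full grid
   m ∈ {2,3}, tau ∈ 1..10, k ∈ 1..10 yields 200 images per record
   (`augment_record()`).
5. **Classification** — a compact 8-layer convolutional network trained with
   Adam, evaluated by stratified 10-fold cross-validation
   (`cross_validate()`), with accuracy, sensitivity (detection rate of
   *normal* fetuses — the positive class here), specificity (detection rate
   of hypoxic fetuses) and AUC.

## Preprocessing rules and their anchors

Three rules, applied in order, each with an exposed threshold
(`preprocess_config()`):

* **Gaps.** A zero-run *strictly longer* than 15 s is spliced out; shorter
  interior runs are linearly interpolated between their flanking samples.
  Runs touching the record ends have no anchor and are trimmed.
* **Stability.** Adjacent samples may differ by at most 25 bpm. A *stable
  part* is operationalised as ≥ 8 consecutive samples (2 s at 4 Hz) whose
  internal steps all stay within 25 bpm — the notion needs an anchor and
  this is deliberately short so genuine variability is preserved; it is a
  config knob (`stable_run_samples`). Samples outside any stable run are
  replaced by linear interpolation between the neighbouring stable runs.
  One case survives that rule: two stable runs at different levels abutting
  directly (typically at a splice junction), where there is nothing to
  interpolate. Those steps are bridged by a short linear ramp over a
  widening window; a record that still cannot be repaired is flagged
  `unrepairable` rather than silently passed.
* **Extremes.** Values outside [50, 200] bpm are replaced by monotone
  piecewise-cubic Hermite interpolation (`splinefun(method = "monoH.FC")`)
  through the surrounding in-range samples; monotonicity keeps the fill
  inside the range of its anchors.

The composition is idempotent and guarantees a zero-free signal inside
[50, 200] bpm — both property-tested.

The analysis segment is the final 13 minutes of the recording
(`select_segment()`). Recordings end at delivery, which is also where the pH
outcome is measured, so the trailing window is the defensible choice; the
length is a parameter (8 minutes is about the shortest informative window,
13 performs best in the source experiments).

## Recurrence-plot choices

* **Norm**: Euclidean.
* **Threshold**: per-point k-nearest-neighbour (the FAN criterion), self
  excluded from the ranking — including it would make k = 1 degenerate. Each
  row of R then contains exactly the diagonal plus (k−1) off-diagonal ones
  when distances are distinct (property-tested against brute force). A
  `mode = "global"` variant (mean of the eps_i, symmetric R) is exposed for
  sensitivity checks.
* **Strictness**: Theta(0) = 0 exactly as stated; a constant signal
  therefore renders an *all-black* plot (all eps_i = 0), which the tests pin
  down.
* **Resampling**: an N×N matrix with N ≈ 3000 must become a 64×64 image and
  no resizing method is stated in the source; this package uses exact
  fractional-area averaging: pixel a covers the cell interval
  [aN/64, (a+1)N/64) on each axis and takes the area-weighted mean of the
  binary cells under it. This preserves the recurrence rate exactly
  (mean(image) = mean(R), tested to 1e-6), degrades gracefully at awkward
  ratios, and reduces to pixel replication for integer upsampling. No
  re-thresholding: pixels are grayscale densities.
* The three network input channels are replications of the one grayscale
  channel; nothing in the source assigns distinct meaning to the channels.

The fused `signal_to_rp()` computes all of this in C++ without materialising
the N×N matrix and is tested to agree with the four-step composition to
floating-point accuracy.

## The synthetic cohort: what it emulates, what it does not

`generate_fhr()` composes baseline (drawn from [120, 150] bpm) +
band-limited Gaussian short-term variability (Gaussian-kernel-smoothed white
noise, 0.6 s kernel) + long-term variability (25 s kernel) + Gaussian-shaped
accelerations (+10–25 bpm, 15–60 s) and decelerations (−10–40 bpm,
20–90 s), clamps the clean signal to [55, 195] bpm, then overwrites
artifacts: zero dropouts (exponential run lengths, mean 8 s, truncated at
40 s) and isolated spikes (±30–100 bpm). A plausibility pH is attached
(normal: uniform [7.20, 7.38]; pathological: [6.95, 7.12]), so the
pH-threshold labelling path is exercised end to end.

Class presets (per hour, bpm):

| parameter | normal | pathological |
|---|---|---|
| short-term variability (sd) | 8 | 2 |
| long-term variability (sd) | 3.5 | 5 |
| accelerations / h | 10 | 2.5 |
| decelerations / h | 0.5 | 2 |
| dropouts / h, spikes / h | 6, 12 | 6, 12 |

Two deliberate modelling points:

* **Why the ratio, not just the amplitude, differs.** A fixed-neighbour-count
  recurrence plot is invariant to multiplying the whole signal by a
  constant: all distances and all thresholds scale together and R is
  unchanged. Two classes differing only in overall variability *amplitude*
  would therefore render nearly identical images. The discriminative
  contrast must sit in the *fast-to-slow variability ratio* — which is also
  the clinical picture: hypoxia suppresses beat-to-beat variability while
  slow undulating patterns persist or become prominent. The presets encode
  exactly that (ratio 8/3.5 versus 2/5), plus the event-rate reversal.
* **What passing tests show.** The generator reproduces the qualitative
  morphology the preprocessing and recurrence stages assume (dropouts,
  spikes, FIGO-like event shapes, 4 Hz sampling) and a class contrast strong
  enough that a simple per-record variance threshold separates ≥ 90% of a
  cohort. It is *not* a physiologically validated cardiotocography
  simulator: no uterine-contraction coupling, no maternal heart rate, no
  autocorrelated artifact processes, no pH–morphology dose-response.
  Passing the cross-validation test demonstrates that the pipeline can
  recover a real class structure of this kind at this sample size — not
  clinical performance on hospital data.

## The network and its training

Architecture `"8"` (the `I-C-P-C-P-F-F-O` chain; `arch_shapes()` reproduces
the 64×64×3 → 60×60×8 → 29×29×8 → 25×25×8 → 12×12×8 → 144 → 2 trace):
each convolution is 5×5 with 8 filters, stride 1, no padding, followed by
batch normalisation and ReLU; pooling is 3×3 average pooling with stride 2;
the first fully connected layer has 144 units (a dense 1152 → 144 map — the
only reading consistent with both the flattened 12×12×8 input and the
144-unit output), dropout at probability 0.8 sits between the two dense
layers, and a softmax over {normal, pathological} closes the chain. The
`"5"` baseline (`I-C-P-F-O`) is the shallow comparator.

Training (`train_config()` defaults): softmax cross-entropy + L2 (1e-4) on
conv/dense weights only; Adam with learning rate 1e-3, squared-gradient
decay 0.6, epsilon 1e-6; mini-batch 64; 10 epochs (an epoch is one full pass
over the training images); SGD (momentum 0.8) and RMSprop are available for
the optimiser comparison. The Adam first-moment decay is not specified by
the source configuration; the conventional 0.9 is used and exposed.

Numerical choices that the source leaves open, settled here and visible in
code:

* **Initialisation**: seeded scaled-uniform fan-in weights,
  U(±sqrt(3/fan_in)); biases zero; batch-norm at identity. The *final*
  classification layer starts at zero so that, with the few dozen optimiser
  steps a small training set affords, the readout is data-driven from step
  one rather than dominated by its random draw.
* **Batch-norm statistics**: training uses batch statistics; evaluation uses
  exponentially weighted running averages (momentum 0.1) that are
  zero-initialised and zero-debiased (divided by 1 − 0.9^t). Without the
  debiasing, short trainings leave the running variance orders of magnitude
  from the true feature variance and evaluation-mode outputs collapse.
* **Input normalisation**: each image is first divided by its own mean
  intensity (its recurrence rate) and then zero-centred with the per-pixel
  training-set mean. The first step matters because fixed-k plots have mean
  ≈ k/N: images from different k grid cells otherwise live on different
  intensity scales, and that scale is a nuisance variable, not class
  information.
* **Determinism**: all stochastic elements (initialisation, shuffling,
  dropout masks, validation split) run off a single seed; training twice
  with the same seed yields bit-identical parameters (tested), and
  evaluation mode (dropout off, running statistics) is exactly
  deterministic.
* **Ties**: equal class probabilities predict `normal` (documented in
  `predict_cnn()`).

## Evaluation protocol

`confusion()` counts with **normal as the positive class** — the source's
convention and the opposite of the usual clinical one; `positive` can be
overridden. `cls_metrics()` reports Acc = (TP+TN)/total, Se = TP/(TP+FN),
Sp = TN/(FP+TN) in percent, with display rounding half-up to 2 decimals and
full precision retained. `roc_auc()` is the trapezoid over the empirical ROC
(equal to Mann–Whitney concordance; tested against an exhaustive pairwise
oracle and against an independent ROC implementation), with a stratified
bootstrap percentile interval in `roc_auc_ci()` (the source does not state
its interval method).

`make_folds()` supports the two protocols:

* `image` mode reproduces the published procedure — images are partitioned
  regardless of their source record. **Warning**: augmented images of one
  record then appear in both training and test folds; this leaks record
  identity and flatters every metric. It exists for replication.
* `record` mode assigns whole records to folds and is the honest
  generalisation estimate; it is the default in `run_pipeline()` and the
  mode used by the package's own cross-validation test.

Folds are stratified by class (the source balances classes globally but does
not say whether folds were stratified; stratification preserves that balance
per fold). Within the training portion a stratified 10% validation split is
held out (the source's split proportion is unstated).

## Problem sizes used by the test suite

The package's automated checks run at sizes a single CPU handles in minutes,
chosen as the package's own study conditions: oracle equivalence on
trajectories up to N = 50 (100 cases), preprocessing invariants on 100
artifact-laden records, augmentation accounting on 105 one-minute records
per class (42,000 images), and cross-validation on a 60-record cohort of
20-minute records with the reduced grid m = 2, tau ∈ {1, 2}, k ∈ {2, 6}
(240 images, record-level 10-fold, both the 8- and 5-layer variants). The
full-scale protocol (552-record clinical database, 200-cell grid, 42,000
images, image-level folds) is reachable with the same functions plus the
documented PhysioNet fetch script.

## Known limitations

* The synthetic generator's class contrast is stylised; real CTU-UHB traces
  carry labour-stage effects, contraction coupling and annotation noise the
  generator does not model, so accuracy on synthetic cohorts does not
  transfer to clinical data.
* The exact numerical behaviour of the original MATLAB training stack
  (initialisation, batch-norm epsilon, Adam first moment) is unknowable from
  the text; published headline numbers are reproducible in distribution at
  full scale, not bit-exactly.
* Image-level folds inflate metrics by construction (see above); published
  high-90s accuracies should be read with that in mind.
* `read_physionet_record()` supports WFDB format 16 (what the target
  database uses); other signal formats are rejected with a clear error.
* Hermite range-repair needs ≥ 4 in-range samples; records failing that (or
  entirely zero, or with no 2-s stable run) error out rather than guess.
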