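---
title: "Interpretable Conv-LSTM classification of intracranial EEG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpretable Conv-LSTM classification of intracranial EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Intracranial EEG (iEEG) review asks, for every short stretch of every
channel: is this normal brain activity, pathological epileptiform activity
(interictal spikes, high-frequency oscillations), or an artifact (muscle
activity, powerline interference)? Convolutional classifiers answer the
question but not the follow-up a reviewer actually cares about: *which part
of the trace drove the call?* `ieegnet` implements a convolutional-LSTM
sequence classifier whose inference output is a **classification heatmap** —
a per-sample time series of class probabilities aligned to the raw trace —
so that abrupt probability changes localize the graphoelements responsible
for the final label.

The package operates on 3-second single-channel segments sampled at 5 kHz
(15,000 samples). Because clinical iEEG of this kind is access-restricted,
the package ships a synthetic generator that emulates the relevant signal
morphologies with exact ground-truth event intervals, so the whole pipeline
is trainable and testable at desk scale.

## Pipeline and model

1. **Segmentation** — constant-length, non-overlapping 3-s windows; a
   trailing remainder is dropped; event intervals are clipped into local
   0-based half-open sample coordinates.
2. **STFT** — Hann window of 256 samples, hop 128, NFFT 1024, one-sided.
   A 15,000-sample segment gives `floor((15000-256)/128)+1 = 116` frames
   with a band spacing of `5000/1024 = 4.883` Hz.
3. **Band truncation** — the DC bin is discarded and the 200 lowest
   remaining bins kept (4.88–976.6 Hz), i.e. content at and above ~1 kHz is
   dropped. Keeping bins 1–200 is the only reading that yields the stated
   200-band spectrogram; it is recorded in every manifest.
4. **Per-band z-scoring** — each band row is centered and scaled by its own
   segment's statistics (population SD; constant rows map to zero). Segment-
   level rather than corpus-level statistics were chosen because inference
   must work on a single unseen segment.
5. **Conv-LSTM** — one convolution layer (default 256 filters spanning all
   200 bands x 7 frames, stride 1, symmetric 3-frame zero padding in time),
   batch normalization, ReLU; the per-frame feature vectors feed a
   unidirectional LSTM (input 256, hidden 128), then a time-distributed dense
   layer with softmax over the 3 classes.
6. **Training** — many-to-one: the cross-entropy loss is evaluated on the
   final frame's probabilities only, against the segment label, with Adam.
   Only segment-level labels exist (nobody annotates every sample), so the
   model must *hold* its decision state to the end of the segment.
7. **Inference** — many-to-many: every frame's softmax is reported, then
   expanded to per-sample resolution (zero-order hold over the 128-sample
   hop, final frame extended to the segment end, first frame back-filled to
   sample 0). Because frame *k*'s window only closes at sample
   `k*128 + 256`, displayed decisions lead the completing data by 256
   samples.

### Numerical and design choices

The underlying description leaves several details open; the package fixes
them as follows (all configurable):

* **Window function**: periodic Hann — the standard compromise for transient
  detection (sidelobe suppression without excessive main-lobe widening).
* **Spectrogram scale**: `log1p` of the linear magnitude is the package
  default. Linear magnitude is Rayleigh-tailed per cell; at desk-scale
  training-set sizes the heavy tail makes per-band z-scores noisy and
  measurably hurts held-out generalization (we verified linear, power and
  log variants on the synthetic benchmark; log generalized best). Linear and
  power modes remain available via `preprocess_segment(mode=)`.
* **Time padding**: symmetric 3-frame zero padding keeps the heatmap length
  equal to the frame count, as full-length display heatmaps require.
  `padding = "valid"` is available. A consequence: the convolution looks up
  to 3 frames ahead, so strict per-frame causality holds only up to that
  lookahead (the prefix-equality test asserts exactly this).
* **LSTM state initialization**: hidden and cell states are drawn
  `U(-0.1, 0.1)` afresh per segment, at training and at inference; the
  randomized start aids gradient propagation and acts as a mild regularizer.
  A degenerate range `c(0,0)` gives the static init.
* **Convolution initialization**: filters start as a band-local filterbank
  (stratified centers across the 200 bands, Gaussian band taper of half-width
  1.5-4 bands, ~3-frame time core). Spectrogram graphoelements — HFO blobs,
  spike ridges, artifact band signatures — occupy a few bands by a couple of
  frames; a dense 200x7 filter sums ~1400 noise cells and drowns such a blob,
  whereas a matched-scale filterbank detects it from the first epoch and lets
  gradient descent refine rather than discover it. Plain He-normal
  (`conv_init = "dense"`) is available.
* **Forget-gate bias**: initialized at 3 (forget activation ~0.95, see
  `build_model`) so the cell integrates with slow decay. With a 3-s segment,
  event evidence must survive up to ~110 LSTM steps to reach the final-frame
  loss; at the conventional bias of 1 the backpropagated signal is attenuated
  by `sigmoid(1)^110` (~1e-15) and the hold-state behavior is unlearnable at
  desk-scale sample sizes — we observed exactly this failure before raising
  the bias. A higher bias (4) saturates the cell so slowly that optimization
  success becomes seed-dependent; 3 was reliable across seeds.
* **Regularization at desk scale**: with a few hundred training segments the
  unregularized model reaches 100% training accuracy by memorizing the
  background noise adjacent to the supervised final frame — measurably
  *destroying* its initial event detectors while doing so — and generalizes
  near chance on the physiological/pathological axis. The desk-scale recipe
  (`desk_train_spec`) therefore combines circular time-shift augmentation
  (each presentation rotates the frame axis by a fresh uniform offset: the
  label is rotation-invariant, the final-frame fingerprint becomes a moving
  target, and events regularly land near the supervised frame where their
  gradient is undamped), feature dropout (0.2) between the conv stack and
  the LSTM, L2 weight decay (1e-3) on weight matrices, and step
  learning-rate decay. All are off by default in a bare `train_spec()` and
  configurable.
* **Batch normalization** uses mini-batch statistics during training and
  frozen running averages (momentum 0.1) at inference.
* **Tie-breaks**: the argmax label breaks ties toward the earlier class in
  `(physiological, pathological, artifact)` order, deterministically.
* **Transition localization**: per-sample argmax runs shorter than
  `min_dwell` (default 640 samples = 128 ms = 5 STFT hops) merge into the
  preceding run; displayed transitions in real recordings persist for
  hundreds of milliseconds, and the default suppresses flicker at the
  hop scale.
* **Envelope display**: zero-phase FIR bandpass (Hamming-windowed, order
  256, stopband > 40 dB after the forward-backward pass) followed by the
  FFT analytic-signal magnitude; defaults 200–600 Hz, the band conventionally
  used to expose HFOs and muscle artifact.

## The synthetic generator

The generator's purpose is to emulate the morphologies the classifier must
distinguish, not any patient population:

* **Background** (physiological): unit-SD pink noise (PSD slope −1) plus a
  13–30 Hz band-limited component contributing a `beta_power` fraction of
  variance (default drawn `U(0.15, 0.45)` per segment) — awake resting iEEG
  with dominant beta.
* **Spike + HFO** (pathological): a biphasic derivative-of-Gaussian
  transient whose main deflection spans a third of the event duration
  (default durations 0.1–0.2 s give 33–67 ms deflections), peak amplitude
  4–8 background SD, with a Hann-windowed sinusoidal burst (default
  120–400 Hz, 0.4x the spike amplitude) riding on it.
* **Muscle artifact**: a flat-spectrum 100–1500 Hz noise burst with
  raised-cosine ramps, 0.5–1.5 s, 3–6 SD.
* **Powerline**: sustained 50 Hz sinusoid plus odd harmonics (relative
  amplitudes 0.2, 0.05), 1–2.5 s, 2–5 SD. Durations shorter than the
  segment are deliberate: after per-band z-scoring a full-segment stationary
  line is nearly invisible, and real mains contamination fluctuates.
* **Mixed-class segments** (optional): a pathological event followed by an
  artifact; the ground-truth label follows the **last** event in time,
  matching final-timestamp classification, and the full event list is
  retained so such segments can be scored separately.

Backgrounds are normalized to SD 1 *before* injection so event amplitudes
are expressed in background-SD units and every test is scale-free. All
waveform families are spectrally synthesized with seeded phases: a dataset
is a bit-reproducible function of its `synthetic_spec`.

What the generator does **not** model: spatial correlation across channels,
patient- or electrode-specific spectra, non-stationary background state
changes (sleep), acquisition-system differences, and real spike/HFO
morphological diversity. Passing the synthetic benchmarks therefore
demonstrates that the implementation learns and localizes the intended
transient classes under controlled conditions — not clinical-grade
performance on hospital recordings, which the original work obtained only
with ~10^5 expert-labeled training segments.

## Desk-scale benchmarks and problem sizes

The package's own end-to-end benchmarks use a reduced model (32 conv
filters, LSTM 32 → 16) trained on 240 synthetic segments (80 per class) and
evaluated on 60 held-out segments, with the `desk_train_spec()` recipe
(`learning_rate 3e-3` with step decay, batch 8, dropout 0.2, weight decay
1e-3, circular shift augmentation, conv learning-rate scale 0.1,
100 epochs).
These sizes keep a full training run to a few minutes on one CPU while
remaining large enough for the parameter-recovery and heatmap-localization
checks to be meaningful. The classifier's held-out macro F1 and the fraction
of pathological segments whose physiological-to-pathological heatmap
transition falls inside `[event onset − 0.3 s, event offset]` are computed
by `scripts/acceptance.R` at run time; the localization tolerance covers the
256-sample display lead (51.2 ms) plus hop granularity.

## The candidate event detector

The annotation aid (`pdm_detect`) bandpasses the raw signal (default
80–600 Hz), takes the analytic-signal envelope, and thresholds it at
`mean + k_sd * SD` of an event-free baseline interval (default `k_sd` 3,
first 0.5 s as baseline); supra-threshold runs separated by under
`merge_gap` (10 ms) merge, and runs of at least `min_event` (10 ms) are
emitted. Whether the original threshold used `mean + k*SD` or `k*SD` alone
is not recoverable from the available description; `mean + k*SD` is this
package's documented reading. Note that raising `k_sd` always shrinks the
total supra-threshold time, and with the default smoothing parameters the
detection *count* is monotone too, though a higher threshold can in
principle split one merged run into two.

## Evaluation conventions

Per-class sensitivity (`TP/(TP+FN)`), positive predictive value
(`TP/(TP+FP)`) and their harmonic mean F1 come from the 3x3 confusion
matrix; the "average" row is the unweighted (macro) mean over classes
computed from unrounded values, and zero-denominator metrics are reported
as missing and excluded with a warning. ROC curves sweep the unique scores
(ties grouped), and the trapezoid AUC equals the Mann-Whitney pair
statistic; PRC AUC uses step-wise summation (average precision) rather than
trapezoids, avoiding the optimistic linear interpolation between recall
levels. One-vs-rest curves score each class by its final-timestamp
probability — the same quantity the classification rule uses.

## Heatmap calibration of early-segment states

Many-to-one training supervises only the final, full-history state of each
segment. The intermediate states that the many-to-many heatmap displays —
in particular the early-segment state, where the integrating cell is still
near its random initialization and little evidence has accumulated — are
never directly supervised. In practice each trained model maps this
"no evidence yet" state to an arbitrary but consistent class: most models
read it as physiological (so a pathological event produces the canonical
physiological-to-pathological transition), but some read it as
artifact-like, in which case the event is still localized by an abrupt
class change whose *from*-state is artifact rather than physiological.
Transition-localization rates of the strict physiological-to-pathological
pattern therefore vary between retrained models even when held-out F1 is
high. We experimented with label-exact suffix augmentation of background
segments to pin the empty state to the physiological class, but it
conflicts with the hold-state semantics (a clean suffix after an early
event must *not* read as physiological) and degraded classification; the
limitation is inherent to final-timestamp supervision and is documented
rather than patched.

## Known limitations

* The network is dense-matrix CPU code: fine at desk scale, not intended for
  multi-day hundred-channel archives.
* Only 5 kHz single-channel processing is supported end to end;
  multi-channel containers are exploded into channels.
* Mixed-class segments are labeled by their final event; no cascade
  re-classification of the heatmap is attempted.
* The EDF writer/reader covers plain 16-bit EDF only (no EDF+ annotations).
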