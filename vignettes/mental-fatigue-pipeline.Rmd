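---
title: "Assessing mental fatigue from fused physiological signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing mental fatigue from fused physiological signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfsense)
```

## The problem

Mental fatigue (MF) degrades reaction time, decision making and
situational awareness in safety-critical operations.  `mfsense`
implements a complete assessment pipeline that fuses raw multichannel
physiological recordings — one ECG trace, one EMG trace, axillary
temperature, six EEG channels (AF3, F3, O1, O2, F4, AF4) and an
eye-tracker block (3-DOF accelerometer, 3-DOF gyroscope, two pupil
diameters) — and classifies 6-second windows of the fused signal with a
small temporal convolutional network.  Smoothing the per-window
classifications over a trailing window turns a two-class classifier into
a continuous MF trace that also exposes intermediate transition states.

This vignette documents the model, its assumptions, the tunable
parameters, the synthetic-data generator used throughout the tests, and
the numerical and design choices that were genuinely open.

## Pipeline and representation

All channels are brought to a common 128 Hz clock (`resample()`, linear
interpolation) and cut by a sliding window of 6 s with 2 s overlap
(`window_spec()`): windows are half-open `[start, start + 6 s)`, start
at multiples of the 4 s step, and trailing partial windows are dropped
so every input has exactly 768 columns.  A session of duration $T$
seconds therefore yields $\lfloor (T-6)/4 \rfloor + 1$ windows, with
consecutive windows sharing 256 columns.

Channel subsets follow the four standard sensor configurations: Case 1
= {ECG, EMG, temperature} (3 rows), Case 2 = eye tracker (8 rows), Case
3 = EEG (6 rows), Case 4 = all 17 rows.  Row order is fixed (ECG, EMG,
temperature, eye block, EEG block) and recorded in every
`fused_segments` object so trained models are portable across sessions.

Because raw-level fusion stacks microvolts next to degrees Celsius and
millimetres, each channel row is z-scored with mean and standard
deviation pooled over the *training* windows only (`fit_normalizer()`;
sd floored at $10^{-8}$ so constant channels map to zero).  Inside
cross-validation the normalizer is refitted on each fold's training
subset, so no statistics leak from validation or test windows.

## The classifier

The network (`model_spec()`) is five blocks of temporal valid
convolution → ReLU → average pooling (kernel 2, stride 2), followed by
a fully connected layer and softmax.  The reference architecture has
256, 128, 64, 32, 32 filters with kernel sizes 3, 5, 7, 9, 9; the
temporal extent evolves 768 → 766 → 383 → 379 → 189 → 183 → 91 → 83 →
41 → 33 → 16.  The convolution treats the channel/filter axis as depth:

$$\mathrm{out}[f, j] = b_f + \sum_{c}\sum_{k} w[f, c, k]\; x[c, j+k-1],$$

which reproduces the 2-D convolution when the kernel spans the full
channel axis.  This is the single most consequential interpretation in
the package: the printed layer parameters are scalar kernel sizes for
time-series rows, so the kernels slide along time only.  The operator
is implemented in the correlation orientation universally used by
convolutional networks; the flipped-kernel form differs only by a
relabelling of the learned weights.  `demo_model_spec()` keeps the same
depth, kernels and extent chain with 16, 16, 8, 8, 8 filters, sized to
train in seconds on one CPU.

## Labels from KSS scores

Each participant reports a Karolinska Sleepiness Scale score (1-9)
before and after the session.  `derive_scale()` maps the lower score to
the low-MF boundary (numeric 0), the higher to the high-MF boundary
(numeric 1), and any KSS levels strictly between become transition
states spaced evenly in (0, 1) — even spacing is a documented choice;
the source material describes the intermediate states only pictorially.
The numeric codomain is fixed to [0, 1] so traces from subjects with
different KSS ranges are comparable.  Equal pre/post scores are a
degenerate scale (no progression to learn) and raise an error.

`assign_labels()` labels the first `floor(0.2 N)` windows of a session
`low` and the last `floor(0.2 N)` `high`; the middle 60% stays
`unknown`, is never trained on, and is what the streaming assessment
probes.  Floor rounding is conservative (boundary labels never bleed
toward the middle) and an empty labeled set is an error.

## Training protocol

`train_cv()` runs Monte-Carlo cross-validation: `folds` independent
seeded stratified 60/20/20 train/validation/test splits at the window
level.  A disjoint 20-fold partition cannot produce 20% test sets, so
repeated random splits are the only consistent reading of the protocol;
the printed fractions are preserved exactly.  Because consecutive
windows overlap by 2 s, window-level random splits share some signal
between train and test; `split_mode = "block"` provides contiguous
per-class splits for leakage-controlled evaluation.

Within a fold, `mf_cnn()` minimizes cross-entropy with Adam plus an L2
weight-decay term (`weight_decay`, default 0.1) on the weights (not the
biases).  The validation-accuracy-driven schedule is: train at least
`min_epochs`; after that, every `lr_patience = 5` consecutive epochs
without improvement multiply the learning rate by 0.8
(`lr_decay_factor = 0.2`), and terminate after `stop_patience = 15`
epochs without improvement.  The mandatory-epoch phase runs at constant
`lr_init`, so an early lucky validation score cannot starve the
optimizer before it has converged.  The best-validation weights are
restored before the test set is touched; among epochs tied at the best
validation accuracy the latest is kept, since later weights have had
longer to consolidate under the decay term.

Weight decay is not cosmetic here.  The demo training sets hold only a
few dozen windows, and a network of a few thousand parameters drives
the training loss to zero within a handful of epochs by memorizing
window-specific structure; test accuracy stays near chance.  Under a
constant learning rate with weight decay, the memorizing components are
steadily shrunk while the class-relevant signal keeps being refreshed
by the gradient, and validation/test accuracy climbs to its ceiling
tens of epochs after the training loss has saturated.  The
`demo_train_config()` schedule (full-batch steps, learning rate 3e-3,
weight decay 0.03, and an epoch budget long enough for this late
generalization) was chosen for exactly this small-sample regime and is
used by the shipped tests; datasets with hundreds of labeled windows
per class train comfortably with the plain defaults.

Optimizer, batch size and initial learning rate are not prescribed by
the protocol; Adam, full-batch demo steps and the rates above are this
package's choices, all configurable in `train_config()` and recorded in
the returned objects.  Ties in the predicted argmax resolve to the
lower class index.

## Streaming assessment

`assess_stream()` replays a recording through the window stream: at
each step $t = 6, 10, 14, \dots$ s the window ending at $t$ is fused,
normalized and classified, and the MF level is the mean over the last 5
steps of the predicted-class indicator (argmax mapped to 0/1).  The
trace is bounded in [0, 1] by construction and, once 5 steps have
elapsed, cannot move by more than 1/5 per step — transition states
emerge from this smoothing rather than being classified directly.
Before 5 steps exist the mean runs over the steps available.  A
`smooth = "probs"` option averages the high-class softmax probability
instead; the indicator reading is the default because it reproduces the
characteristic stepped-then-smoothed traces.  Note the step cadence is
the 4 s window step, so 5 steps span roughly 20-22 s of signal; a
trailing 30 s is sometimes quoted for this smoothing and the
discrepancy is surfaced here rather than resolved.

## Introspection by deconvolution

`project_activation()` maps a chosen kernel's activation at any layer
back to input coordinates: all other activation maps at that layer are
zeroed, then for each block down to the input the average pooling is
reversed by uniform redistribution (each pooled value split equally
across its window — the adjoint of average pooling; the cited reversal
technique uses max-pooling switches, which do not exist here), ReLU is
applied, and the transposed (flipped-kernel) convolution with the
layer's own weights moves one block down.  Biases are omitted on the
reverse pass, the standard deconvolution convention.  `top_kernel()`
selects the kernel with the largest activation-map L2 norm (ties to the
lowest index) and `channel_norms()` reports per-channel L2 norms of a
projection — the measurement primitive for judging which input channel
a kernel relies on; which channel matters is subject- and
data-specific, and no claim about real recordings is built in.

## The synthetic generator

No public recordings accompany this problem, so `simulate_session()`
generates the full 17-channel suite with a controllable latent fatigue
trajectory $\lambda(t) \in [0, 1]$ (`fatigue_profile()`, piecewise
linear).  At level $\lambda$ every modality's parameters are the convex
combination $(1-\lambda)\,\text{low} + \lambda\,\text{high}$ of the
`generator_config()` endpoints:

* **EEG** — per canonical band (delta 0.3-4, theta 4-8, alpha 8-13,
  beta 13-30 Hz), a mixture of 8 random-frequency, random-phase
  sinusoids whose joint RMS amplitude tracks the band amplitude, plus
  Gaussian noise.  Defaults raise alpha and theta amplitude with
  fatigue (10 → 20 µV against a constant 20 µV delta and 5 µV beta,
  noise sd 5 µV), consistent with the well-established association
  between fatigue and low-frequency spectral power.  Each component's
  phase follows a Brownian walk (`eeg_phase_diffusion`, default 0.2
  rad²/s, i.e. a coherence time near 10 s): real cortical rhythms are
  not deterministic oscillators, and without finite coherence every
  window is a time-shifted copy of one fixed waveform — a structure a
  window-level classifier can exploit in ways no real EEG would permit.
  The spectral broadening this causes (~0.03 Hz) is negligible against
  the band widths, so band-power arithmetic is unaffected.
* **ECG** — a Gaussian-pulse train at the interpolated heart rate
  (default 70 → 60 bpm); morphological realism is deliberately out of
  scope.
* **EMG** — amplitude-modulated broadband noise (envelope 1.0 → 0.5),
  reflecting declining contraction intensity.
* **Temperature** — slow linear drift (default −0.2 °C/h) plus noise.
* **Eye tracker** — pupil diameter is baseline plus a λ-scaled delta
  (default 0: no established direction under fatigue, so the parameter
  is exposed neutrally), and the accelerometer/gyroscope channels are
  neutral noise.

Identical configurations (including the seed) reproduce bit-identical
recordings.  `band_power()` (periodogram integration over a band) is
the generator's validation utility and the independent oracle used by
the tests: a threshold on mean EEG alpha power must separate the
labeled windows perfectly before the network is asked to.

What the generator does **not** emulate: realistic EEG artifacts
(ocular, muscular, line noise), heart-rate variability structure,
inter-channel correlation topography, and any nonstationarity beyond
the latent trajectory.  Passing tests on this data therefore certify
the pipeline's mechanics — segmentation, leakage-free normalization,
training, smoothing, reversal arithmetic — not field performance on
human recordings.

## Demo study conditions and problem sizes

The shipped tests and the acceptance script use: 10-minute sessions at
128 Hz (149 windows; 29 labeled per class), latent step from 0 to 1 at
mid-session, KSS 2 → 4, Case 3, the reduced `demo_model_spec()`, and
5-fold cross-validation under `demo_train_config()` — the package's
demo configuration.  Where more labeled data is needed the tests pool a
pair of seeded sessions with `combine_segments()`.  A full-scale run
(60-90 minute sessions, the 256-filter model, 20 folds) is the same
code with larger arguments.

## Known limitations

* Linear-interpolation resampling applies no anti-alias filter; all
  synthetic content is below Nyquist by construction, but real data
  resampled from higher rates should be low-passed first.
* Random window-level splits share overlap between train and test;
  use `split_mode = "block"` to quantify the effect.
* Only pre/post KSS reports are consumed; intermediate in-session
  self-reports would refine the scale but are out of scope.
* The assessment replays recordings from files; live sensor I/O is not
  implemented.
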