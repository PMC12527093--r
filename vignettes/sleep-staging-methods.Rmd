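---
title: "Methods: wavelet scalograms and a lightweight attention CNN for sleep staging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet scalograms and a lightweight attention CNN for sleep staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lmcsleep)
```

## The problem

Overnight polysomnography (PSG) is scored by experts into five AASM stages
— wake (W), three non-REM depths (N1, N2, N3) and REM — one label per 30 s
epoch. `lmcsleep` implements an automatic scorer for the three-channel
Sleep-EDF montage (EEG Fpz-Cz, EEG Pz-Oz, horizontal EOG, all at 100 Hz):
each epoch is converted into a time-frequency image per channel and
classified independently by a small convolutional network. The package
covers the whole chain — EDF input, R&K-to-AASM label mapping, Morlet CWT
preprocessing, the network with its training protocol, evaluation
statistics, and a synthetic PSG generator that lets everything run
end-to-end without any recording download.

## Preprocessing: Morlet scalograms

Each channel of each epoch (3000 samples = 30 s x 100 Hz) is transformed
with the complex Morlet wavelet
$\phi(t) = e^{-t^2/2} e^{i\omega_0 t}$,
discretized at integer scales $a = 1,\dots,32$ as
$\psi_a[k] = a^{-1/2}\,\phi(k/a)$ on a symmetric grid wide enough for the
Gaussian envelope to fall below $10^{-8}$. Coefficients are computed by
same-length zero-padded convolution with the conjugated, time-reversed
wavelet (via FFT), and the scalogram is the coefficient magnitude — the
common non-negative convention for such maps.

Relevant numerical facts, all fixed once and tested:

* **Scale-to-frequency mapping.** With the $1/\sqrt a$ (L2) normalization
  the pseudo-frequency of scale $a$ is $f(a) = \omega_0 f_s /(2\pi a)$:
  about 95.5 Hz at $a=1$ down to about 3.0 Hz at $a=32$ for
  $\omega_0 = 6$ (the standard admissibility-safe center frequency; the
  value is exposed in `scalogram_config()`). Note the set therefore does
  **not** reach the lower delta band (0.5-2 Hz): a 2 Hz tone has its
  nominal scale at ~47.7, outside the set, and its achievable peak sits at
  the boundary scale 32. The tests assert scale-accurate peak recovery for
  5/10/20 Hz tones and the boundary behavior at 2 Hz.
* **Scale-1 aliasing.** Sampling $\phi(k/a)$ on the integer grid at $a=1$
  places the oscillation at 6 rad/sample, beyond $\pi$; it aliases to
  ~4.5 Hz, so scale 1 responds spuriously to slow signals. This is
  inherent to time-domain sampling of the Morlet at unit scale (any
  implementation that samples the mother wavelet this way shares it); the
  alias-free scales are $a \ge \omega_0/\pi \approx 1.91$.
* **Median downsampling.** The 3000-point time axis is compressed to 200
  points by non-overlapping 15-sample windows, each replaced by its median
  (for even windows, the mean of the two central order statistics). A
  median of 15 is the 8th order statistic: a single arbitrarily large
  outlier can move it at most to an adjacent order statistic and never
  drags it toward the outlier, which is the precise sense in which this
  step is robust. Mean and max pooling exist behind a flag purely for the
  comparison harness.
* **Normalization.** The network input is z-scored per channel and per
  epoch ((x - mean)/(sd + 1e-8), population SD), so absolute microvolt
  scales — and EDF physical calibration — cancel. Constant maps normalize
  to zero.

The result is one `[3, 200, 32]` tensor per epoch. Preprocessing is fully
deterministic.

## The network

The classifier is a lightweight CNN with four pieces:

1. **Multi-scale dilated stem (MSDC).** Three parallel 3x3 convolutions at
   stride 2 with dilation rates 1/2/3 (padding = dilation), each followed
   by batch norm; a dilation-$d$ branch sees a $(2d{+}1)^2$ receptive
   field at constant parameter cost. Branch outputs are concatenated along
   channels (3 x 64 = 192) and fused by a 1x1 convolution back to 64
   channels, with batch norm and ReLU. The fusion conv reconciles channel
   concatenation with the 64-channel body; an additive fusion mode
   (summing branches, no fusion conv) is available for the comparison
   harness.
2. **Depthwise-separable residual body.** A ResNet18-style ladder: four
   stages of widths 64/128/256/512, two basic blocks each, stride 2 at the
   first block of stages 2-4 with a 1x1-conv + batch-norm shortcut. Every
   3x3 convolution in a block is factorized into a depthwise stage (one
   3x3 kernel per channel — no channel mixing) and a pointwise 1x1 stage
   (channel mixing only), each followed by batch norm. Shortcut 1x1 convs
   stay standard (they are already pointwise). All convolutions are
   bias-free.
3. **CBAM attention**, applied once after stage 4, sequentially: channel
   attention (global average- and max-pooled descriptors through a shared
   bias-free bottleneck MLP with reduction 16, summed, sigmoid) followed
   by spatial attention (channel-wise mean and max maps, 7x7 conv with
   bias, sigmoid). Sequential channel-then-spatial is the canonical CBAM
   composition and is what the package implements.
4. **Head**: global average pooling to a 512-vector, dropout (p = 0.5),
   fully connected layer to 5 classes, softmax.

Nominal "224x224-style" layer tables for this family of networks quote
spatial sizes 112, 56, ..., 7; the actual 200x32 input follows the same
stride schedule (100x16, 50x8 after pooling, then 50x8, 25x4, 13x2, 7x1),
and the adaptive global pool absorbs the difference.

Parameter accounting is exact and tested: the full pinned model has
**1,492,840** trainable scalars (1.49 M), the no-MSDC ablation (standard
7x7 stride-2 stem) **1,484,392** (1.48 M), and the plain 18-layer residual
baseline in its 1000-class configuration **11,689,512** (11.69 M). The
depthwise-separable factorization is where the ~8x reduction comes from:
a 64-to-64 3x3 conv costs 36,864 weights, its factorized form 4,672.

## Training protocol

Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$) at learning rate $5\times10^{-6}$,
minibatch 64, weighted cross-entropy with class weights inversely
proportional to stage counts, $w_c = N/(K n_c)$ (their frequency-weighted
mean is exactly 1), L2 regularization with weight $10^{-3}$, early stopping
when validation accuracy has not improved for 20 consecutive epochs
(strictly-greater improvement; ties do not reset patience), with the best
checkpoint restored. Design choices where the protocol leaves room:

* The learning rate is unusually small for Adam from scratch; it is
  implemented as specified and exposed in `train_config()`.
* L2 is applied as optimizer-coupled weight decay on convolution, FC and
  attention weights only — not on batch-norm parameters or biases —
  the standard practice for ResNet-family training.
* No maximum epoch budget is prescribed; the default is 200.
* Cross-validation splits are subject-wise (shuffled subjects dealt
  round-robin into 10 folds): epochs of one subject-night never appear on
  both sides of a fold, which is the field-standard leakage guard. A
  record-wise mode exists behind a flag for comparability. Fold confusion
  matrices are pooled by summation; summaries are reported both pooled and
  fold-averaged (mean and SD), since published tables mix the two
  conventions.
* Seeding covers initialization, shuffling and dropout; runs are
  bit-reproducible on a single device.

Because no deep-learning framework is available to R in this environment,
the layers and their backward passes are implemented in the package itself
(Rcpp/RcppArmadillo kernels for convolution and pooling, R for the rest).
Every forward operator is tested against naive nested-loop oracles and
every backward pass against central finite differences.

## Evaluation

`confusion_matrix()` uses the fixed W, N1, N2, N3, REM order (rows = true
stage). Per-class precision, recall and F1 come from the usual TP/FP/FN
definitions with a flagged zero convention for degenerate denominators, so
macro-F1 stays defined on sparse folds. Overall metrics are accuracy
(trace/N), macro-F1 (unweighted mean of the five unrounded F1 values) and
Cohen's $\kappa = (p_o - p_e)/(1 - p_e)$ with
$p_e = \sum_i r_i c_i / N^2$; the single-class case ($p_e = 1$) reports
$\kappa$ as `NA`. The package ships the published pooled SleepEDF-20
confusion matrix as a plain-text fixture; `verify_reference_metrics()`
recomputes accuracy 88.2%, $\kappa$ 0.84, macro-F1 82.4% and the per-class
rows from it. Two printed per-class F1 values (W 93.7, N1 51.5) are not
consistent with that matrix (the matrix gives 93.6 and 50.8, presumably a
fold-averaged vs pooled discrepancy in the source table); only
matrix-consistent values are asserted.

## The synthetic generator

`synth_dataset()` emulates just enough PSG physiology for the pipeline to
be exercised honestly:

* **Stage signatures** (defaults in `stage_profiles()`): continuous
  8-12 Hz alpha plus frequent blink deflections for W; low-amplitude
  4-7 Hz theta for N1; theta background plus 12-14 Hz spindle bursts of
  0.5-1 s (duty cycle 0.12) for N2; high-amplitude 0.5-2 Hz delta for N3;
  4-8 Hz theta with large slow EOG deflections (EOG channel only) for REM.
  Components are sinusoids with jittered frequency and phase plus Gaussian
  broadband noise; amplitudes are arbitrary units since normalization
  removes scale.
* **Hypnogram structure.** Stage sequences use exact per-stage quotas
  (largest-remainder rounding of the requested proportions — the
  SleepEDF-20 distribution 21.1/6.5/41.3/13.2/17.9% by default) arranged
  in geometric runs with persistence 0.85 (mean bout ~6.7 epochs). Exact
  quotas keep realized proportions at the request even per subject; the
  run structure makes subject-wise splits meaningfully harder than i.i.d.
  shuffling. About 2% of epochs are replaced by MOVEMENT/UNKNOWN artifacts
  to exercise annotation filtering.
* **What it does not model**: 1/f background spectra, K-complex and vertex
  morphology, inter-subject variability beyond RNG jitter, electrode
  artifacts, or realistic stage-transition grammars. The stages are
  linearly separable in band-power space by construction (a nearest-
  centroid classifier on five log band powers clears 80%, tested), which
  guarantees the end-to-end learning check is achievable. Passing that
  check therefore demonstrates that the pipeline, gradients and training
  loop work — not that the architecture reaches any particular accuracy
  on real PSG, which would require the actual Sleep-EDF recordings and
  orders of magnitude more compute.

## Problem sizes used by the test suite

The tests run the full pipeline at reduced scale, chosen once as
representative: operator-equivalence oracles on tensors up to `[4, 8, 8]`;
training unit tests on directly constructed separable bundles (~50-60
epochs, widths 8/8/16/16); the end-to-end learning check on 20 synthetic
subjects x 100 epochs with stage widths 16/32/64/128, subject-wise 5-fold
cross-validation, learning rate raised to 1e-3 with batch 64, an epoch
budget of 2 with patience 1, and the pooled accuracy compared against 60%
(chance is 20%) as the median over three training seeds. The ablation
harness smoke-runs all four variants at width 8/8/16/16 on a ~100-epoch
bundle.

## Known limitations

* Epochs are classified independently; there is no sequence model over
  neighboring epochs, and no pretrained weights.
* The EDF layer targets the Sleep-EDF montage: no resampling, alternative
  montages, or artifact rejection. Wake trimming around the sleep period
  is available (`trim_wake`) but off by default, since the protocol does
  not state it.
* Scale 1 of the wavelet bank is aliased (above) and the scale set stops
  at ~3 Hz; both are properties of the pinned discretization, documented
  rather than silently corrected.
* The training engine is CPU-only and double-precision; it is built for
  correctness and moderate scale, not for GPU-class throughput.
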