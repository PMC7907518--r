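---
title: "Acoustic screening of dementia: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acoustic screening of dementia: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demscreen)
```

## The problem

Alzheimer's dementia (AD) leaves early, measurable traces in spontaneous
speech: patients pause more often and for longer, speak more slowly, and show
flattened pitch variability. `demscreen` implements two purely acoustic
systems that classify a speaker as AD or non-AD from a single recording,
without transcripts or language-specific resources:

1. **Embedding + majority vote.** The recording is cut into non-overlapping
   0.96 s patches. Each patch becomes a 96 × 64 log-mel spectrogram (96
   frames of 10 ms, 64 mel bands), is mapped to a 128-dimensional embedding,
   and the embeddings are PCA-whitened to 128 components. A segment-level
   classifier — RBF SVM, linear SVM, perceptron, SGD-trained MLP or cosine
   1-NN — labels each patch, and the subject receives the label predicted for
   the majority of their patches.
2. **DemCNN.** A raw-waveform classifier: the audio is decimated stagewise by
   factors (4, 4, 2) behind anti-aliasing low-pass filters (16 kHz → 500 Hz),
   cropped/padded to a fixed window, and fed to a six-block one-dimensional
   convolutional network (conv → ReLU → batch norm → dropout), global average
   pooling, and a two-node dense output trained with cross-entropy. Training
   runs in two steps: batch size 32 at a fixed rate, then batch size 2 at a
   rate selected automatically from a learning-rate range test.

Both systems are evaluated subject-disjointly: 80% of speakers (stratified by
class) train the system, the remaining 20% are predicted.

## The synthetic corpus

The real corpora for this task (DementiaBank / the ADReSS challenge subset)
are access-controlled, so the package ships a seeded generator of speech-like
audio in which the two classes differ exactly in the prosodic statistics the
systems are meant to detect. A recording is a syllable/pause alternation:

* voiced bursts — harmonic tones whose fundamental is drawn per syllable from
  Normal(`f0_mean_hz`, `f0_sd_hz`), partials kept below 4 kHz, 10 ms Hann
  on/off ramps, lognormal jitter on the inter-onset interval and Gaussian
  jitter on the amplitude;
* silences — every syllable boundary carries a short gap, and with
  probability `pause_prob` an additional pause with exponentially distributed
  duration of mean `pause_dur_mean_s`;
* a faint Gaussian noise floor (sd 0.002) and final peak normalization.

The default class profiles encode the direction of every clinically reported
marker: the AD profile has a lower syllable rate (2.2 vs 4.0 bursts/s), a
higher pause probability (0.5 vs 0.15), longer pauses (1.1 vs 0.4 s mean) and
lower f0 variability (8 vs 25 Hz sd) than the non-AD profile, at an equal
mean f0 of 120 Hz. These magnitudes are deliberately generous — an "easy"
condition that a working pipeline must separate almost perfectly. `"hard"`
halves the gap; `"null"` makes the profiles identical, which is how the test
suite verifies that no information leaks from labels into predictions.
Corpora default to 30 s per subject (≈ 31 patches), a length that keeps test
runtimes reasonable while giving the majority vote a meaningful electorate.

What the generator does **not** emulate: formant structure, coarticulation,
channel/recording noise, interviewer cross-talk, or any lexical content.
Passing tests on this corpus demonstrate that the pipelines detect prosodic
pause/rate/variability structure end to end; they say nothing about accuracy
on real clinical audio.

Determinism is a contract: a corpus is a pure function of its spec, with
per-subject seeds derived by a stated hash
`(seed * 131071 + index * 7919) mod (2^31 - 1)`.

## Front-end constants

The patch geometry is fixed by the embedding front-end convention: 0.96 s
patches, 25 ms analysis window, 10 ms hop, 64 triangular mel filters spanning
125–7500 Hz on the HTK mel scale (`m = 2595 log10(1 + f/700)`), and
`log(mel energy + 0.01)` compression. One wrinkle is documented here because
it is easy to miss: 96 frames of a 400-sample window at a 160-sample hop
need 15600 samples, while a 0.96 s segment has 15360; segments are therefore
symmetrically zero-padded by 240 samples before framing so the patch is
exactly 96 × 64.

The canonical audio representation is mono, 16 kHz, peak-normalized.
16 kHz is the standard rate for this patch geometry and makes the DemCNN
front-end land at 500 Hz after the (4, 4, 2) decimation; peak normalization
is the simplest deterministic loudness contract. Multi-channel audio is
averaged to mono. All constants are arguments, not magic numbers.

The built-in embedder is a deterministic surrogate: a fixed seeded Gaussian
random projection of the flattened patch to 128 dimensions followed by tanh.
It performs no learning and is not a substitute for a trained deep
embedding's representational quality; it exists so that the pipeline around
the embedder — patching, log-mel, whitening, classification, voting,
speaker-disjoint evaluation — is fully testable and reproducible offline.
Any deterministic patch-to-128-vector function can be plugged in through
`custom_embedder()`, which is the adapter point for checkpoint-backed
embedders.

## Whitening

`fit_whitening()` computes the principal axes of the centered training
embeddings and rescales each kept component to unit variance. It is always
fitted on training-subject segments only and then applied, frozen, to test
segments; the experiment runner enforces this ordering. Refitting on the
training partition (rather than shipping fixed statistics) is the only
self-contained choice, and whitened features are given to all five
classifiers uniformly. Rank-deficient inputs (fewer independent directions
than requested components) raise an error instructing the caller to reduce
`n_components` — silent pseudo-inversion would make downstream variances
meaningless.

## Segment classifiers

Defaults follow common tool conventions: RBF SVM with the "scale" bandwidth
heuristic `gamma = 1/(d · var(X))` and cost 1; linear SVM with cost 1;
perceptron trained by the classic mistake-driven rule until convergence or
100 epochs; an MLP with **one hidden layer of width 20** trained by plain
minibatch SGD (600 iterations, step 0.001, logistic output); and 1-nearest
neighbor under cosine distance (`1 − cosine similarity`, zero vectors at
maximal distance 2). The width-20 reading of "20 hidden layers" deserves a
note: a 20-layer unregularized network trained by plain SGD at step 0.001
for 600 iterations would not train at all, while a single hidden layer of 20
units is exactly what the common tooling parameter with that phrasing
configures; the width is an ordinary hyperparameter either way. Every
decision tie in every classifier breaks toward NONAD — a fixed, documented
rule that favors the healthy class and keeps runs reproducible; the same
rule settles majority-vote ties.

## DemCNN numerics

* **Decimation.** Each stage low-passes at 0.9 × the new Nyquist with an
  8th-order Butterworth filter run forward and backward (zero phase, squared
  magnitude response), then keeps every f-th sample. The composite factor is
  exactly 32; tone probes in the test suite verify ≤ 1 dB passband ripple at
  50 Hz and ≥ 40 dB stopband rejection at 1 kHz.
* **Input window.** Recordings are center-cropped or symmetrically
  zero-padded to 2^14 = 16384 post-decimation samples (≈ 32.8 s at 500 Hz),
  so the default 30 s synthetic recordings fit entirely.
* **Architecture defaults.** Channels (16, 32, 32, 64, 64, 128), kernel 9,
  stride 2, dropout 0.1 in blocks 1–4 and 0.3 in blocks 5–6 (the larger late
  dropout is the regularizer that keeps train and test behavior close);
  global average pooling makes the dense head independent of input length.
  He initialization, seeded; batch-norm eps 1e-5, momentum 0.1.
* **Implementation.** Convolutions are im2col gathers followed by BLAS
  matrix products, with activations stored channels-by-positions so batch
  statistics are row means. The per-block ReLU/batch-norm/dropout
  arithmetic and the col2im gradient scatter run in compiled (Rcpp)
  kernels fused into single passes; dropout draws from the R RNG, so runs
  stay reproducible under `set.seed`. Gradients are exact — the test suite
  checks them against central finite differences at tolerance 1e-3 on the
  symmetric relative error.
* **Two-step schedule.** Step 1: batch 32, rate 0.1, 2 cycles × 8 epochs.
  Step 2: batch 2, 2 cycles × 8 epochs at a rate chosen by the range test.
  The "cycles/lengths" pair is exposed as four integers so either a per-step
  or a total reading of a cycle budget is configurable; the batch-size-2
  phase is treated as a second *training* phase, the only reading under
  which it affects optimization.
* **Rate selection.** The range test sweeps exponentially spaced rates, one
  seeded mini-batch SGD step per rate on a transient copy, and records the
  mini-batch loss; `select_lr()` smooths with a centered 3-point moving
  average and returns the rate of steepest negative slope against log-rate,
  restricted to rates strictly below the curve minimum (at and beyond it the
  curve bends toward divergence). A sweep with no descending stretch is an
  error; `fit_two_step()` falls back to one tenth of the step-1 rate with a
  warning in that case. On a convex quadratic with curvature *a*, gradient
  descent is stable exactly below 2/*a*; the test suite uses this closed
  form to pin both the divergence behavior and the selection region.
* **Batch-norm calibration.** After training, population statistics are
  re-estimated with one dropout-free pass over the training set.
  Momentum-averaged running statistics are collected under dropout noise
  and, in step 2, from batches of two; on small corpora the resulting
  train/inference mismatch is large enough to flip borderline subjects, and
  recalibration removes it deterministically.
* **Degenerate inputs.** Non-finite training loss aborts with a condition
  object carrying the finite history collected so far (batch norm makes the
  network nearly scale-invariant, so this effectively requires
  overflow-level rates); recordings shorter than the filter length refuse to
  decimate; single-class training sets are rejected.

## Evaluation protocol

One 80/20 speaker-disjoint stratified split per run (per-class train size
`round(0.8 n)`), seeded. AD is the positive class for precision, recall and
F1; zero denominators report 0 with a warning rather than NaN. The embedding
system reports both subject-level (post-vote) and segment-level metrics,
since the two levels answer different questions about where discrimination
happens. DemCNN makes one whole-recording decision per subject and does not
vote. Reports carry no timestamps, so byte-identical reruns are a testable
contract.

## Problem sizes in the test suite

Unit tests run the network at reduced geometry (input 256–512 samples, 4–8
channels) through the same code paths. The end-to-end checks use 10 subjects
per class × 30 s (3 corpus seeds) for the separability property, 20 per
class (5 seeds) for the null/no-leakage property, and 4 per class for the
overfit-capability check — sizes chosen to give the statistical assertions
reasonable power at desk-scale runtimes.

## Known limitations

* The surrogate embedder carries no learned acoustic knowledge; absolute
  accuracies on the synthetic corpus say nothing about clinical data.
* The synthetic corpus separates classes by prosody alone and is deliberately
  easy at the default gap.
* Single 80/20 split, no cross-validation or significance testing; the
  balanced two-class design means class weighting is out of scope.
* CPU-only; the default DemCNN geometry trains a 20-subject corpus in the
  order of a minute per seed rather than seconds.
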