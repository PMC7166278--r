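---
title: "A 1-D convolutional network for EEG seizure detection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A 1-D convolutional network for EEG seizure detection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegcnn)
```

## The problem and the data model

Epileptic seizure activity shows up in the electroencephalogram (EEG) as
high-amplitude rhythmic discharges that are qualitatively different from
normal background activity and from the interictal (between-seizure)
patterns of epilepsy patients. The classic benchmark corpus for automatic
seizure detection consists of five sets of 100 single-channel recordings
each, sampled at 173.61 Hz for 23.6 s (4097 samples): sets A and B from
healthy volunteers (eyes open / eyes closed), C and D from epilepsy
patients during seizure-free intervals (C from the hippocampal formation of
the opposite hemisphere, D from within the epileptogenic zone), and E
containing seizure activity only. The sets also circulate under their
original directory names Z, O, N, F and S; both spellings are accepted
everywhere in this package.

Deep networks need more training examples than 500 recordings provide. The
widely used tabular redistribution of the corpus therefore cuts every
4097-sample recording into 23 non-overlapping chunks of 178 samples
(about one second), discarding the trailing 3 samples; the chunk is the
unit of classification, giving 2300 labelled examples per set.
`chunk_segment()` implements exactly this convention, and `load_chunk_table()`
reads the 178-column CSV form directly. The tabular form encodes its class
labels as integers 1–5; because the correspondence to set letters is not
documented by the redistributors, the mapping is configurable
(`DEFAULT_LABEL_MAP`, 1 → E … 5 → A) and is echoed whenever a table is read.

Classification tasks group the five sets into 2, 3 or 5 classes.
`list_tasks()` holds the 20 standard combinations (14 two-class, 5
three-class, 1 five-class; every one includes the seizure set E). Grouped
tasks such as "ABCD vs. E" are deliberately left imbalanced — no resampling
or class weighting is applied anywhere.

## The network

Each input chunk is standardized to zero mean and unit variance and passes
through three identical convolutional blocks followed by three fully
connected (FC) layers. A block is, in order:

1. **1-D convolution**, valid padding, stride 1. The layer computes sliding
   dot products (cross-correlation); because kernels are learned, the
   flip-vs-no-flip distinction in the convolution definition is
   unobservable after training, and the no-flip convention of every deep
   learning framework is used (`cross_correlate()` is the scalar
   reference).
2. **Batch normalization (BN)**: per channel, the mini-batch response `H`
   is normalized as `H' = (H - mu) / sigma` with
   `sigma = sqrt(delta + Var[H])`; the stabilizer `delta` sits *inside* the
   square root, so the divisor never falls below `sqrt(delta)`. A learnable
   per-channel scale and shift follows, as in standard BN.
3. **ReLU**, `f(x) = max(0, x)`.
4. **Dropout** (rate 0.2 in all conv blocks), placed after the activation
   and before pooling.
5. **Max pooling**, size 2, stride 2, *ceil mode*: odd lengths are
   right-padded so the last window holds just the final element.

Valid convolution and ceil-mode pooling are not arbitrary choices: they are
the only combination consistent with the reference shape table
(178 → 139 with a 40-tap kernel forces valid padding; 139 → 70 and 17 → 9
force ceil-mode pooling). `shape_trace()` computes the resulting
layer-by-layer shapes; `realized_shape_trace()` measures them on the built
network, and the test suite asserts the two agree for every preset.

After flattening (720 features for M7), FC1 and FC2 use ReLU followed by
dropout, and FC3 is a softmax layer with one neuron per class. Softmax is
computed with max-subtraction so that large scores cannot overflow.

The eight preset configurations M1–M8 share the kernel counts 20/40/80 and
conv dropout 0.2, and span receptive fields 5/3/3 vs 40/20/10, FC widths
32/16 vs 64/32, and FC dropout 0.2 vs 0.5. M7 (40/20/10, 64/32, dropout
0.2) is the selected model.

```{r}
shape_trace(model_config("M7", n_classes = 5))
```

## Training protocol

Training minimizes categorical cross-entropy with mini-batch stochastic
gradient descent under the Adam optimizer: learning rate 5e-4, beta1 0.9,
beta2 0.999, batch size 100, 300 epochs. Data are reshuffled every epoch
with a seeded generator, and the final incomplete mini-batch is used rather
than dropped (it wastes no data; the protocol does not say either way).
There is no learning-rate schedule, early stopping or weight decay, and the
final-epoch model is the one evaluated — the protocol names none of these,
so the simplest reading is implemented. Scaled-down epoch counts are a
configuration value (`train_config(epochs = ...)`), never hard-coded, so
the full protocol is one argument away.

Choices the protocol leaves open, and what this package does:

* **Adam epsilon**: 1e-7.
* **Weight initialization**: fan-based (Glorot) uniform with a configurable
  seed.
* **BN stabilizer** `delta`: 1e-3 ("small positive" is all that is
  specified).
* **BN inference statistics**: exponential running averages of the batch
  mean and variance with momentum 0.99, accumulated from zero and
  *debiased* by `1 - 0.99^t` at inference — the same bias correction Adam
  applies to its moment estimates. Without the correction the zero
  initialization dominates the running statistics for the first few
  hundred updates, and a scaled-down run (tens of epochs on a few hundred
  chunks) can show perfect training accuracy yet collapse to a single
  class at inference. For full-length runs the corrected and uncorrected
  estimates coincide to numerical precision.
* **Conv biases**: omitted. BN recentres every channel immediately after
  the convolution, so an additive conv bias receives exactly zero gradient
  in training mode; FC layers keep their biases.
* **Prediction ties**: argmax ties break toward the lowest class index
  (deterministic).
* **Degenerate inputs**: a constant chunk has zero variance and cannot be
  standardized; it is rejected with an error rather than silently mapped
  to zeros.

The implementation itself is dense linear algebra: activations are
(batch, length, channels) arrays, each convolution is a single BLAS matrix
product over an im2col expansion (the gather and its scatter-add adjoint
are small compiled kernels), and backpropagation follows the standard
layer-by-layer chain rule. With dropout disabled and BN in inference mode
the forward pass is deterministic; training runs are deterministic for a
fixed seed on a fixed platform (floating-point reduction order can differ
across BLAS builds).

## Evaluation conventions

Every k-class result is decomposed into k one-vs-rest binary problems with
counts TP/TN/FP/FN, from which accuracy, precision, sensitivity,
specificity and F1 are computed as percentages. The headline "overall"
figures are **macro averages** — unweighted means of the per-class
one-vs-rest metrics. This convention is not guessable from the formulas
alone, but it is forced by the published three-class result: the overall
accuracy printed there (98.06) equals the mean of the three per-class
one-vs-rest accuracies (98.32, 97.54, 98.32), while the pooled trace/total
fraction is 97.09. Micro (pooled-count) variants are computed alongside and
always labelled as such. Two identities are useful sanity checks and are
enforced in the tests: macro one-vs-rest accuracy equals
`1 - 2*offdiag/(k*total)` for any confusion matrix, and for balanced
classes macro sensitivity equals micro accuracy.

Metrics with zero denominators (an empty class or an empty predicted
column) are returned as `NA` and propagate into macro averages with a
warning; silently substituting 0 would corrupt the averages.

Cross-validation is stratified 10-fold at chunk level: within each class,
chunks are shuffled with a seeded generator and dealt round-robin, so
per-class fold sizes differ by at most one and 2300 chunks per class yield
exactly 230 per fold. Per-fold accuracy is the macro overall accuracy of
that fold's confusion matrix; the summed matrix over folds (each chunk is
tested exactly once) gives the per-class report. Note that chunk-level
folding places chunks of the same recording in both training and test
sets; the within-record correlation this introduces is a known property of
the tabular-redistribution protocol, not an accident. For a stricter
generalization estimate `make_folds(level = "record")` deals whole
recordings instead. Likewise, per-chunk standardization (the default)
cannot leak statistics across folds; the alternative dataset-level mode
(`standardize_chunks(method = "dataset")`) accepts externally fitted
statistics so it can be restricted to training folds.

All metric computation is in full precision; presentation rounds half away
from zero to two decimals (`round_half_up()`), matching the convention of
the published tables.

```{r}
overall_metrics(reference_confusion_bde())
```

## The synthetic generator

Real recordings cannot be redistributed with the package, so
`simulate_segment()` provides a seeded surrogate: a sum of fixed-frequency
sinusoids with uniformly random phases, Poisson-placed biphasic spike
transients (a 15-sample triangular wave, ~86 ms), and white Gaussian
noise, rounded to integer ADC counts. The per-class defaults
(`default_signal_params()`) encode the qualitative picture of the five
sets — E as large-amplitude rhythmic delta/theta activity with frequent
sharp transients, C and D as moderate slow backgrounds with
interictal-like spikes (D spikier and slower), A and B as low-amplitude
alpha backgrounds with B much cleaner and stronger (eyes closed) than A.
Because chunks are standardized before classification, absolute amplitude
is invisible to the model; the classes are separable through waveform
*shape* — relative noise level, spectral content and spike density — which
is what makes the generator a meaningful end-to-end probe rather than a
trivial amplitude threshold.

The parameters were fixed once, from first principles, and are **not**
fitted to real EEG; the generator makes no attempt at 1/f spectra,
autoregressive structure, non-stationarity within a recording, or
inter-record variability beyond phase/spike/noise randomness. Passing the
synthetic learning checks therefore demonstrates that the pipeline —
chunking, standardization, the network, training, folding, metrics — is
wired correctly and can learn class structure of this general kind; it
says nothing quantitative about accuracy on real EEG. Reproducing the
published real-data accuracies requires the real corpus (an external
download) and the full 300-epoch stochastic protocol;
`scripts/full_protocol.R` runs that experiment when pointed at the data
and reports per-task deviation from the published grid
(`reference_cv_accuracies()`).

## Problem sizes used by the tests

The test-suite and acceptance-script learning checks use 200 chunks per
class (nine synthetic recordings' worth), M7, 30 epochs and full 10-fold
cross-validation — large enough to demonstrate learning far above chance
(the thresholds are 95% for two-class A vs. E, 60% for five-class against
a 20% chance level), small enough to run on a single CPU in minutes. All
other tests run on matrices or datasets of at most a few hundred rows.

## Known limitations

* Single-channel, fixed-length recordings only; no EDF/BDF clinical
  formats, no multi-channel montages, no artifact rejection or filtering
  (the method consumes raw signals by design).
* No ensembling, no alternative architectures, no data augmentation; the
  overlapping-chunk idea sometimes used to enlarge the corpus further is
  out of scope.
* CPU-only dense algebra. It is fast enough for the corpus scale this
  method targets; it is not a general deep-learning framework.
* Training determinism is best-effort: bit-identical results are
  guaranteed only for a fixed BLAS/platform combination.
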