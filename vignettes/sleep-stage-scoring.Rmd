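---
title: "Residual-network sleep stage scoring: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residual-network sleep stage scoring: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepstager)
```

## The problem

Rodent sleep studies score vigilance states — Wake, NREM sleep, REM sleep —
from paired EEG and EMG recordings in fixed 4-second epochs. Manual scoring by
waveform and spectrum inspection is the bottleneck of the field: days of signal
per animal, hours of scorer time per day of signal. `sleepstager` implements an
automated scorer built on a two-dimensional residual convolutional network that
consumes the raw preprocessed voltages of one epoch, with no context from
neighbouring epochs, and emits a probability for each of the three states.

The package covers the complete workflow: reading raw voltage tables and
per-epoch score files, resampling and epoching, the preprocessing chain, a
synthetic signal generator for testing, the network and its training protocol
(stratified five-fold cross-validation, augmentation, Adam), the evaluation
metric suite, and hypnogram inference with stage-minute binning.

## Preprocessing model

Each scored epoch enters as 1,024 samples per channel (4 s at 256 Hz) and is
reduced to the `(256, 2)` array the network consumes:

1. **Fourfold polyphase downsampling** of both channels to 64 Hz. The
   resampler upsamples by `p`, filters with a Kaiser-windowed (beta = 5) sinc
   low-pass of half-length `10 * max(p, q)` taps, and keeps every `q`-th
   sample. The window and length follow the widely used convention of
   `resample_poly` in scientific Python, and our implementation agrees with
   that reference to ~1e-15 on shared inputs. We additionally normalize every
   polyphase branch to unit DC gain, so constant signals are reproduced
   exactly away from the edges (the unnormalized design leaves ~1e-4 ripple at
   a 64/125 ratio). The same resampler handles 500 Hz telemetry exports
   (ratio 64/125) before epoching.
2. **EMG high-pass**: order-4 Butterworth, 0.5 Hz cutoff, applied
   forward-backward (zero phase) so epoch-internal timing is untouched. The
   order is our choice (unstated in the protocol we follow); zero-phase
   application avoids phase distortion at the cost of squaring the magnitude
   response, which only sharpens the intended drift rejection. Only the EMG is
   filtered: sub-hertz EEG content is delta-band signal, not drift.
3. **Baseline correction** of both channels by subtracting the per-epoch mean.
   "Baseline subtraction" is ambiguous (mean, median, or detrend); we use the
   minimal reading — mean subtraction — applied after filtering, and document
   it here as a deliberate choice. Output means are zero to machine precision.
4. **Artifact exclusion**: epochs whose score token is anything other than
   `W`, `N`, `R` are labelled `A` and dropped before training; counts are
   logged.

Filtering is per epoch, not per recording, because the training pipeline
operates on shuffled epoch arrays; edge effects of the short filters are
accepted and all fidelity checks in the test suite measure away from epoch
edges.

`welch_psd()` (Hann window, 50% overlap, density scaling) supports the
spectral checks; no installed R package provides a Welch estimator, so it is
implemented here and validated against closed forms.

## Network

The classifier is a stack of residual blocks over an input of shape
`(256, 2, 1)` — time by channel by map. Each block is

```
conv(2,1) -> batch norm -> dropout -> ReLU
conv(2,1) -> batch norm -> dropout -> ReLU
conv(2,1) -> batch norm
+ shortcut (identity, or 1x1 conv + batch norm when the width changes)
-> ReLU
```

with stride (1,1) and "same" padding throughout, so the time/channel extent
never changes and the elementwise merge is always shape-compatible. The
default network has seven blocks with widths 8, 16, ..., 512, followed by
global average pooling over the time-by-channel extent and a dense softmax
layer with three outputs. Dropout is present but inert at the default rate 0.

The printed kernel specification is ambiguous between `(2, 1)` =
(time, channel) and its transpose; we fix the kernel to span two steps along
the **time** axis by default and expose `kernel_axis = "channel"` for the
transposed reading rather than resolving the ambiguity silently. Note that
with a `(2, 1)` kernel the EEG and EMG columns are processed by shared
weights but never mixed until the pooling stage.

There is no deep-learning framework in this package's dependency set; the
engine (convolution expressed as shifted matrix products, batch
normalization, residual merges, global average pooling, softmax
cross-entropy, backpropagation and Adam) is implemented on base R matrix
algebra and verified by numerical gradient checking in the test suite.

### Numerical choices

* Convolution weights: He-normal initialization (the stack is ReLU-based),
  under a recorded seed.
* Final dense layer: zero-initialized, so a freshly built model emits exactly
  uniform class probabilities; this removes initialization bias from the
  class priors and makes tie-breaking behaviour testable.
* Batch normalization: epsilon 1e-3; running statistics with retain-momentum
  0.9 per update, used in (deterministic) inference mode.
* Softmax cross-entropy with probabilities clipped at 1e-12.
* Argmax ties at inference break toward the earlier class in (W, N, R) order.

## Training protocol

Training follows the published protocol exactly: Adam (default learning rate
1e-6), categorical cross-entropy, minibatches (default 128), up to 50 passes
with the epoch order reshuffled every pass, augmentation applied to training
batches only, the best parameters checkpointed by the monitored loss, and the
learning rate multiplied by 0.5 (floor 1e-8, our values; the protocol states
only the three-pass patience) whenever the monitored training loss fails to
improve for three consecutive passes. The monitored quantity for both the
plateau rule and the checkpoint is the training loss; the protocol names
training loss for the plateau rule and leaves the checkpoint metric unstated,
so we use the same quantity for both and note the choice here.

Cross-validation uses stratified folds built by dealing each class's shuffled
indices round-robin into k = 5 bins, which guarantees per-class counts within
one sample of `n_class / k` in every fold; each fold is an 80/20
train/validation partition. The final deployment model is instead trained on
the full dataset (with an internal stratified 80/20 monitor split) and the
final-pass parameters are kept, matching the "final model after 50 epochs"
convention.

### Augmentation

Three stochastic transforms, composed in the order scale, translate, noise
(noise last so its calibration is meaningful), applied with fresh draws per
epoch per pass, never to validation data, and never to labels:

* independent per-channel amplitude scaling, factors uniform in [0.8, 1.2];
* one circular time shift per epoch, uniform in ±64 of 256 samples, applied
  to both channels identically ("temporally yoked"); circular rolling
  preserves signal energy and suits the rolling-window reading of the
  protocol;
* additive Gaussian noise at 5% of each channel's per-epoch SD.

The protocol names the three transforms but none of their magnitudes; the
values above are conservative package defaults, exposed in
`augment_config()`.

## Synthetic data generator

The generator exists so that every stage of the pipeline is testable without
any animal data. It emulates:

* stage-dependent spectra — Wake: mixed 2–20 Hz EEG at 30 uV RMS with high
  (40 uV) EMG tone; NREM: delta 0.5–4 Hz EEG at 80 uV with low (8 uV) EMG;
  REM: theta 5–9 Hz EEG at 35 uV with near-absent (2 uV) EMG. Each epoch is a
  coherent oscillation at a frequency drawn from the stage band (60% of EEG
  power), band-limited noise in the same band (35%), and a small broadband
  floor (5%);
* bout structure via a Markov chain whose default transition matrix has
  stationary distribution exactly (0.50, 0.42, 0.08) over (W, N, R) — Wake
  predominating, REM rare, REM entered only from NREM;
* artifacts (2% of epochs by default): wake-like signals with large
  transient spikes;
* baseline drift (10 uV at 0.1 Hz) on both channels; optional mains
  contamination (off by default).

The amplitudes are round figures in the range seen in mouse telemetry; they
were fixed once when the generator was written. A two-rule threshold baseline
(EMG RMS, then EEG delta/theta power ratio) classifies this data almost
perfectly, which certifies that the learning task is solvable — so a network
that fails to learn it indicates a pipeline defect, not an impossible task.

What the generator does **not** emulate: 1/f background spectra, spindles and
slow-oscillation waveforms, state-transition dynamics inside an epoch,
inter-animal variability, electrode artifacts correlated across channels, or
circadian structure. Passing the synthetic tests therefore demonstrates that
the pipeline is mechanically and statistically correct, not that the shipped
defaults reach any particular accuracy on real recordings.

## Reduced-scale validation and a known optimization limit

The test suite trains reduced models (2 blocks, 4 starting maps, learning
rate 1e-4, at most 10 passes over ~3,000 synthetic epochs, minibatch 4) so
the whole cycle fits in CPU minutes; these sizes are the package's standing
choices for its own validation and are pinned in the tests.

One empirical finding from this configuration is documented here because it
is a property of the optimizer, not a defect. Adam moves each parameter by at
most about one learning rate per update, so a run with `S` updates can move a
weight by roughly `S * lr` at most. In the reduced configuration the global
average pool emits only 8 features whose batch-normalized scale is ~0.4, and
the REM class holds 8% of the epochs: flipping the REM argmax against the
learned Wake/NREM prior advantage (~1.7 logits) requires dense-layer weight
norms near 10, i.e. a few times 10^4 updates at learning rate 1e-4 — more
than 10 passes of ~2,400 training epochs can deliver at any stable batch
size. The symptom is characteristic: validation loss falls steadily (to
~0.17) while validation accuracy pins at exactly the Wake + NREM fraction
(92.4%), with the REM probability rising but not yet winning. Single-sample
batches would provide enough updates, but batch normalization then degenerates
to per-sample statistics and the learned solution no longer transfers to
inference mode. Training accuracy, fresh-recording accuracy above 90%, and
the augmentation-robustness property are all reached within the reduced
budget; the >95% validation-accuracy figure needs roughly twice as many
passes (at minibatch 4 the flip occurs around pass 19, and validation
accuracy is 100% from pass 20 on). The full-size
configuration does not share this arithmetic: with 512 pooled features the
same per-weight movement produces a ~64-fold larger logit swing.

## Evaluation

`confusion_matrix()` (rows = truth, columns = prediction, order W/N/R) feeds
per-stage one-vs-rest accuracy, precision, recall and F1 (percent), per-stage
one-vs-rest Cohen's kappa and overall kappa on the full 3x3 table — the
one-vs-rest collapse for per-stage kappa is our documented reading of
per-stage kappa reporting. `categorical_cross_entropy()` and
`explained_variance()` complete the per-fold report; `fold_summary()` adds
mean and SEM (sample SD / sqrt(n)) rows.

For cross-classifier comparison, `overall_weighted_metrics()` implements the
recall-weighted overall precision, precision-weighted overall recall, and
their harmonic-mean F1. Applied to the per-stage values in
`comparison_benchmark`, these formulas reproduce the published overall
figures of MC-SleepNet, Random Forest, MASC, the LSTM model and the
large-cohort MC-SleepNet row at 1-decimal precision. They do **not**
reproduce the residual-network stager's own published overall recall (97.9,
which exceeds all three of its per-stage recalls and therefore cannot be any
weighted mean of them); the package reports the formula value and flags the
printed figure as unresolved. The published overall F1 (96.0) is consistent
with the printed overall precision/recall pair.

Inference produces a `hypnogram` (per-epoch stage + probability triple),
`bin_hypnogram()` aggregates minutes per stage in 2-h bins (full bins sum to
120 minutes; trailing partial bins are flagged and excluded from correlation
by default), and `concordance()` reports per-stage and pooled Pearson r
against manually scored bins.

## Known limitations

* Input formats are delimited text voltage tables and one-token-per-line
  score files; there is no EDF reader in the dependency set, so EDF exports
  must be converted upstream. The score-file dialect (first token of each
  non-empty line) is an assumption documented at `parse_stage_labels()`.
* The pure-R engine is practical for the reduced test-scale models and for
  inference, but full-size (7-block) training at realistic dataset sizes
  calls for a GPU framework; the package's value at full scale is the
  preprocessing, protocol, and evaluation machinery plus a reference
  implementation of the architecture.
* Per-stage kappa, the checkpoint metric, filter order, baseline definition,
  and augmentation magnitudes are documented package decisions where the
  protocol we follow is silent.
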