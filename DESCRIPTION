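Package: sleepstager
Title: Residual-Network Sleep Stage Scoring for Mouse EEG/EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scores 4-second epochs of paired mouse electroencephalogram (EEG)
    and electromyogram (EMG) recordings into Wake, NREM and REM vigilance
    states with a two-dimensional residual convolutional neural network.
    Provides the complete preprocessing chain (polyphase anti-aliased
    downsampling, zero-phase Butterworth high-pass filtering of the EMG,
    per-epoch baseline correction, artifact exclusion), a Markov-chain
    synthetic EEG/EMG generator with stage-dependent spectra for testing,
    training-time data augmentation (independent per-channel amplitude
    scaling, temporally yoked circular translation, additive Gaussian noise),
    stratified five-fold cross-validation with Adam optimization and
    learning-rate-on-plateau reduction, a full multiclass evaluation suite
    (per-stage and overall precision, recall, F1, accuracy, Cohen's kappa,
    categorical cross-entropy, explained variance, recall/precision-weighted
    overall metrics), and hypnogram inference with 2-hour stage-minute
    binning and Pearson concordance against manual scores. The network engine
    (2D convolution, batch normalization, residual merge, global average
    pooling, softmax, backpropagation, Adam) is implemented on base R matrix
    algebra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
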