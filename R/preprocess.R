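#' Downsample one 4-s epoch fourfold
#'
#' Reduces a 1024-sample epoch (256 Hz) to 256 samples (64 Hz) by polyphase
#' anti-aliased resampling. Fourfold reduction keeps all spectral content
#' below the new 32 Hz Nyquist, which covers the delta (0.5-4 Hz) and theta
#' (5-9 Hz) bands that carry the stage information.
#'
#' @param series Numeric vector of exactly 1024 samples.
#' @param factor Integer reduction factor (default 4).
#' @return Numeric vector of `length(series) / factor` samples.
#' @export
downsample_epoch <- function(series, factor = 4L) {
  if (length(series) != 1024L) {
    stop("downsample_epoch expects exactly 1024 samples, got ", length(series))
  }
  resample_polyphase(series, 1L, as.integer(factor))
}

#' Zero-phase Butterworth high-pass for the EMG channel
#'
#' Removes slow drift and DC offset from the downsampled EMG with an
#' order-`order` Butterworth high-pass at `cutoff_hz`, applied forward and
#' backward (`signal::filtfilt`) so the epoch-internal timing is not
#' distorted. Only the EMG channel is filtered; EEG low-frequency content
#' (delta band) is signal, not drift.
#'
#' @param emg Numeric vector (one epoch of EMG at `fs` Hz).
#' @param fs Sampling rate in Hz (default 64).
#' @param cutoff_hz High-pass cutoff (default 0.5 Hz).
#' @param order Filter order (default 4).
#' @return Filtered series of the same length.
#' @export
highpass_emg <- function(emg, fs = 64, cutoff_hz = 0.5, order = 4L) {
  if (anyNA(emg) || !all(is.finite(emg))) stop("EMG input must be finite")
  if (cutoff_hz >= fs / 2) stop("cutoff must lie below the Nyquist rate")
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "high")
  as.numeric(signal::filtfilt(bf, as.numeric(emg)))
}

#' Per-epoch baseline correction
#'
#' Subtracts the epoch mean, the minimal reading of "baseline subtraction"
#' for short windows. The output mean is zero by construction.
#'
#' @param series Numeric vector.
#' @return The series minus its mean.
#' @export
baseline_correct <- function(series) {
  if (anyNA(series) || !all(is.finite(series))) stop("input must be finite")
  series - mean(series)
}

#' Remove artifact-labelled epochs
#'
#' Drops all and only the epochs labelled `A`, preserving the relative order
#' of the remainder. The number of removed epochs is reported via `message()`;
#' an all-artifact input yields an empty set with a warning.
#'
#' @param epochs An `epoch_set` from [segment_into_epochs()].
#' @return The filtered `epoch_set`.
#' @export
remove_artifact_epochs <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  keep <- is.na(epochs$labels) | epochs$labels != "A"
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    message("removed ", n_drop, " artifact epoch(s) of ", length(keep))
  }
  if (!any(keep)) warning("all epochs were artifacts; returning an empty set")
  epochs$eeg <- epochs$eeg[keep, , drop = FALSE]
  epochs$emg <- epochs$emg[keep, , drop = FALSE]
  epochs$labels <- epochs$labels[keep]
  epochs
}

#' Assemble the model input tensor from raw epochs
#'
#' Runs the full per-epoch chain: fourfold downsampling of both channels
#' (1024 to 256 samples), zero-phase 0.5 Hz Butterworth high-pass of the EMG
#' only, per-epoch baseline correction of both channels, artifact removal;
#' then stacks the result into the `(N, 256, 2)` array (channel 1 = EEG,
#' channel 2 = EMG) with one-hot `(N, 3)` labels consumed by the network.
#'
#' @param epochs An `epoch_set` of 1024-sample epochs at 256 Hz.
#' @param filter_spec List with elements `cutoff_hz` and `order` for the EMG
#'   high-pass (defaults 0.5 Hz, order 4).
#' @return An object of class `epoch_dataset`: `signals` array
#'   `(N, 256, 2)`, `labels` integer matrix `(N, 3)` (all `NA` for unscored
#'   input), `epoch_rate_hz = 64`, `provenance` character vector of source
#'   ids.
#' @export
preprocess_dataset <- function(epochs,
                               filter_spec = list(cutoff_hz = 0.5, order = 4L)) {
  stopifnot(inherits(epochs, "epoch_set"))
  epochs <- remove_artifact_epochs(epochs)
  n <- nrow(epochs$eeg)
  signals <- array(NA_real_, dim = c(n, 256L, 2L))
  for (i in seq_len(n)) {
    eeg <- downsample_epoch(epochs$eeg[i, ])
    emg <- downsample_epoch(epochs$emg[i, ])
    emg <- highpass_emg(emg, fs = 64,
                        cutoff_hz = filter_spec$cutoff_hz,
                        order = filter_spec$order)
    signals[i, , 1L] <- baseline_correct(eeg)
    signals[i, , 2L] <- baseline_correct(emg)
  }
  labels <- if (all(is.na(epochs$labels))) {
    matrix(NA_integer_, nrow = n, ncol = 3L,
           dimnames = list(NULL, c("W", "N", "R")))
  } else {
    stage_onehot(epochs$labels)
  }
  structure(
    list(signals = signals,
         labels = labels,
         stages = epochs$labels,
         epoch_rate_hz = 64,
         provenance = rep(epochs$source_id, n)),
    class = "epoch_dataset"
  )
}

#' @export
print.epoch_dataset <- function(x, ...) {
  cat(sprintf("<epoch_dataset> %d epochs x %d samples x 2 channels @ %g Hz\n",
              dim(x$signals)[1L], dim(x$signals)[2L], x$epoch_rate_hz))
  if (!all(is.na(x$stages))) {
    tab <- table(factor(x$stages, levels = c("W", "N", "R")))
    cat("  stages:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Welch power spectral density
#'
#' Averaged modified periodograms: the series is cut into `nperseg`-sample
#' segments with fractional `overlap`, each segment is detrended (mean
#' removed), Hann-windowed, and its periodogram accumulated. Scaling follows
#' the usual density convention (power per Hz), so a unit-amplitude sinusoid
#' integrates to 1/2 over frequency.
#'
#' @param series Numeric vector, length at least 64.
#' @param fs Sampling rate in Hz.
#' @param nperseg Segment length (default `min(256, length(series))`).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return A data.frame with columns `frequency` (0 to `fs/2`) and `power`.
#' @export
welch_psd <- function(series, fs, nperseg = NULL, overlap = 0.5) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 64L) stop("welch_psd needs at least 64 samples, got ", n)
  if (is.null(nperseg)) nperseg <- min(256L, n)
  nperseg <- as.integer(nperseg)
  step <- max(1L, as.integer(round(nperseg * (1 - overlap))))
  starts <- seq.int(1L, n - nperseg + 1L, by = step)

  # periodic Hann window of length nperseg
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nperseg) - 1L) / nperseg)
  u <- sum(w^2)                       # window power normalization
  nfreq <- nperseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- series[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg)[seq_len(nfreq)])^2
    acc <- acc + sp
  }
  pow <- acc / (length(starts) * u * fs)
  # one-sided: double everything except DC (and Nyquist when nperseg even)
  dbl <- rep(2, nfreq); dbl[1L] <- 1
  if (nperseg %% 2L == 0L) dbl[nfreq] <- 1
  data.frame(frequency = (seq_len(nfreq) - 1L) * fs / nperseg,
             power = pow * dbl)
}

#' Band power from a PSD curve
#'
#' Integrates (trapezoid rule) the PSD over `[fmin, fmax]`.
#'
#' @param psd A data.frame from [welch_psd()].
#' @param fmin,fmax Band edges in Hz.
#' @return Scalar band power.
#' @export
band_power <- function(psd, fmin, fmax) {
  sel <- psd$frequency >= fmin & psd$frequency <= fmax
  f <- psd$frequency[sel]
  p <- psd$power[sel]
  if (length(f) < 2L) return(sum(p))
  sum(diff(f) * (utils::head(p, -1L) + utils::tail(p, -1L)) / 2)
}
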