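#' Stage-dependent signal parameters for the synthetic generator
#'
#' Defaults emulate the canonical mouse polysomnography signatures: Wake has
#' mixed-frequency (2-20 Hz) low-amplitude EEG with high EMG tone; NREM has
#' delta-dominant (0.5-4 Hz) high-amplitude EEG with low EMG; REM has
#' theta-dominant (5-9 Hz) low-amplitude EEG with near-absent EMG tone.
#' Amplitudes are root-mean-square microvolts. `sine_frac` is the fraction of
#' EEG RMS carried by a coherent oscillation at a frequency drawn from the
#' stage band (the rest is band-limited noise); `broadband_frac` is a small
#' wideband floor. `drift_uv`/`drift_hz` add slow baseline wander to both
#' channels; `mains_uv`/`mains_hz` optionally add line-frequency
#' contamination (off by default). Artifact epochs get `spike_uv`
#' large-amplitude transients.
#'
#' @param wake,nrem,rem Per-stage lists with `eeg_band` (Hz, length 2),
#'   `eeg_rms` (uV) and `emg_rms` (uV).
#' @param sine_frac,broadband_frac EEG power composition fractions.
#' @param drift_uv,drift_hz Baseline drift amplitude (uV) and frequency (Hz).
#' @param mains_uv,mains_hz Mains contamination amplitude (uV; 0 disables)
#'   and frequency (50 or 60 Hz).
#' @param spike_uv Artifact transient amplitude (uV).
#' @return An object of class `stage_signal_params`.
#' @export
stage_signal_params <- function(
    wake = list(eeg_band = c(2, 20), eeg_rms = 30, emg_rms = 40),
    nrem = list(eeg_band = c(0.5, 4), eeg_rms = 80, emg_rms = 8),
    rem  = list(eeg_band = c(5, 9),  eeg_rms = 35, emg_rms = 2),
    sine_frac = 0.6, broadband_frac = 0.05,
    drift_uv = 10, drift_hz = 0.1,
    mains_uv = 0, mains_hz = 60,
    spike_uv = 400) {
  p <- list(W = wake, N = nrem, R = rem)
  for (s in names(p)) {
    band <- p[[s]]$eeg_band
    if (length(band) != 2L || band[1L] <= 0 || band[2L] >= 32 ||
        band[1L] >= band[2L]) {
      stop("eeg_band for ", s, " must lie within (0, 32) Hz")
    }
  }
  if (!(p$W$emg_rms > p$N$emg_rms && p$N$emg_rms > p$R$emg_rms)) {
    stop("EMG tone must be ordered Wake > NREM > REM")
  }
  structure(
    c(p, list(sine_frac = sine_frac, broadband_frac = broadband_frac,
              drift_uv = drift_uv, drift_hz = drift_hz,
              mains_uv = mains_uv, mains_hz = mains_hz,
              spike_uv = spike_uv)),
    class = "stage_signal_params"
  )
}

#' Markov transition model over vigilance states
#'
#' Row-stochastic 3x3 matrix over (W, N, R) used to sample bout-structured
#' stage sequences. The default matrix has stationary distribution exactly
#' (0.50, 0.42, 0.08), reflecting the Wake-predominant class imbalance of
#' mouse recordings, with REM entered only from NREM. Artifacts are overlaid
#' independently per epoch at `artifact_rate`.
#'
#' @param transition 3x3 row-stochastic matrix, rows/columns ordered (W,N,R).
#' @param artifact_rate Per-epoch probability of an artifact label.
#' @param seed Integer seed governing all generator randomness.
#' @return An object of class `transition_model`.
#' @export
transition_model <- function(
    transition = rbind(W = c(0.930000, 0.070000, 0.000000),
                       N = c(3 / 70,   0.900000, 4 / 70),
                       R = c(0.212500, 0.087500, 0.700000)),
    artifact_rate = 0.02,
    seed = 1L) {
  transition <- as.matrix(transition)
  if (!all(dim(transition) == c(3L, 3L)) || any(transition < 0) ||
      any(abs(rowSums(transition) - 1) > 1e-8)) {
    stop("transition must be a 3x3 row-stochastic matrix")
  }
  if (artifact_rate < 0 || artifact_rate >= 1) {
    stop("artifact_rate must be in [0, 1)")
  }
  dimnames(transition) <- list(c("W", "N", "R"), c("W", "N", "R"))
  structure(list(transition = transition,
                 artifact_rate = artifact_rate,
                 seed = as.integer(seed)),
            class = "transition_model")
}

#' Stationary distribution of a transition matrix
#'
#' Left eigenvector of the transition matrix with eigenvalue 1, normalized to
#' sum to one.
#'
#' @param transition Row-stochastic square matrix.
#' @return Named numeric vector.
#' @export
stationary_distribution <- function(transition) {
  e <- eigen(t(transition))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  stats::setNames(v / sum(v), rownames(transition))
}

#' Sample a bout-structured stage sequence
#'
#' Draws the initial state from the stationary distribution, then follows the
#' Markov chain; artifact labels (`A`) are overlaid independently per epoch
#' at the model's `artifact_rate` (the underlying chain continues beneath
#' them). Reproducible from the model seed.
#'
#' @param n_epochs Number of 4-s epochs (> 0).
#' @param model A [transition_model()].
#' @param init Optional fixed initial state (`"W"`, `"N"` or `"R"`); by
#'   default the initial state is drawn from the stationary distribution.
#' @return Character vector of codes in `{W, N, R, A}` with the underlying
#'   (artifact-free) sequence in attribute `"underlying"`.
#' @export
sample_stage_sequence <- function(n_epochs, model = transition_model(),
                                  init = NULL) {
  stopifnot(inherits(model, "transition_model"), n_epochs > 0)
  n_epochs <- as.integer(n_epochs)
  states <- c("W", "N", "R")
  P <- model$transition
  out <- character(n_epochs)
  withr_seed <- .with_seed(model$seed, {
    s <- if (is.null(init)) {
      sample(3L, 1L, prob = stationary_distribution(P))
    } else {
      match(match.arg(init, states), states)
    }
    out[1L] <- states[s]
    for (i in seq_len(n_epochs - 1L)) {
      s <- sample(3L, 1L, prob = P[s, ])
      out[i + 1L] <- states[s]
    }
    art <- stats::runif(n_epochs) < model$artifact_rate
    labelled <- ifelse(art, "A", out)
    list(labelled = labelled, underlying = out)
  })
  structure(withr_seed$labelled, underlying = withr_seed$underlying)
}

# evaluate `expr` under a temporary RNG seed, restoring the caller's state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# band-limited unit-RMS Gaussian noise via FFT masking
.band_noise <- function(n, fs, band) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)                 # two-sided frequency axis
  X[f < band[1L] | f > band[2L]] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) return(numeric(n))
  y / s
}

#' Synthesize one 4-s EEG/EMG epoch
#'
#' EEG is a coherent oscillation at a frequency drawn uniformly from the
#' stage band plus band-limited noise in the same band and a small broadband
#' floor, scaled to the stage RMS; EMG is broadband noise at the stage RMS.
#' Both channels receive slow baseline drift, and optional mains
#' contamination. Artifact epochs (`A`) are wake-like signals with
#' large-amplitude transient spikes on both channels. Bit-reproducible from
#' `(stage, seed)`.
#'
#' @param stage One of `"W"`, `"N"`, `"R"`, `"A"`.
#' @param params A [stage_signal_params()].
#' @param seed Integer seed.
#' @param n_samples Samples per channel (default 1024 = 4 s at 256 Hz).
#' @param fs Sampling rate (default 256 Hz).
#' @return List with numeric `eeg` and `emg` (length `n_samples`) and the
#'   `stage` code.
#' @export
synthesize_epoch <- function(stage, params = stage_signal_params(), seed = 1L,
                             n_samples = 1024L, fs = 256) {
  stopifnot(stage %in% c("W", "N", "R", "A"))
  .with_seed(seed, {
    base_stage <- if (stage == "A") "W" else stage
    sp <- params[[base_stage]]
    t <- (seq_len(n_samples) - 1L) / fs

    f0 <- stats::runif(1L, sp$eeg_band[1L], sp$eeg_band[2L])
    phase <- stats::runif(1L, 0, 2 * pi)
    sine <- sqrt(2) * sin(2 * pi * f0 * t + phase)   # unit RMS
    bn <- .band_noise(n_samples, fs, sp$eeg_band)
    wb <- stats::rnorm(n_samples)
    wb <- if (stats::sd(wb) > 0) wb / stats::sd(wb) else wb
    sf <- params$sine_frac
    bb <- params$broadband_frac
    eeg <- sp$eeg_rms * (sqrt(sf) * sine + sqrt(1 - sf - bb) * bn + sqrt(bb) * wb)

    emg <- sp$emg_rms * stats::rnorm(n_samples)

    drift_phase <- stats::runif(1L, 0, 2 * pi)
    drift <- params$drift_uv * sin(2 * pi * params$drift_hz * t + drift_phase)
    eeg <- eeg + drift
    emg <- emg + drift
    if (params$mains_uv > 0) {
      mains <- params$mains_uv * sin(2 * pi * params$mains_hz * t)
      eeg <- eeg + mains
      emg <- emg + mains
    }
    if (stage == "A") {
      k <- sample.int(10L, 1L) + 4L
      pos <- sample.int(n_samples, k)
      amp <- params$spike_uv * stats::runif(k, 0.5, 1) *
        sign(stats::runif(k) - 0.5)
      eeg[pos] <- eeg[pos] + amp
      emg[pos] <- emg[pos] + amp
    }
    list(eeg = eeg, emg = emg, stage = stage)
  })
}

#' Synthesize a recording and write it in the reader's formats
#'
#' Samples a stage sequence from the transition model, synthesizes each
#' epoch's signals, concatenates them into a continuous 256 Hz recording and
#' writes three files to `out_dir`: `<basename>_signals.csv` (two-column
#' voltage table), `<basename>_stages.txt` (one label token per line) and
#' `<basename>_manifest.txt` (key = value provenance: seed, n_epochs,
#' artifact rate, parameter summary).
#'
#' @param n_epochs Number of 4-s epochs.
#' @param model A [transition_model()].
#' @param params A [stage_signal_params()].
#' @param out_dir Writable directory.
#' @param basename File stem (default "synthetic").
#' @return Invisibly, a list with `signal_path`, `label_path`,
#'   `manifest_path` and the sampled `stages`.
#' @export
synthesize_recording <- function(n_epochs, model = transition_model(),
                                 params = stage_signal_params(),
                                 out_dir = tempdir(), basename = "synthetic") {
  if (!dir.exists(out_dir)) stop("output directory does not exist: ", out_dir)
  stages <- sample_stage_sequence(n_epochs, model)
  ep <- synthesize_epoch_set(stages, params, seed = model$seed)
  rec <- raw_recording(as.numeric(t(ep$eeg)), as.numeric(t(ep$emg)),
                       sample_rate_hz = 256,
                       source_id = basename)
  signal_path <- file.path(out_dir, paste0(basename, "_signals.csv"))
  label_path <- file.path(out_dir, paste0(basename, "_stages.txt"))
  manifest_path <- file.path(out_dir, paste0(basename, "_manifest.txt"))
  write_voltage_table(rec, signal_path)
  writeLines(as.character(stages), label_path)
  writeLines(c(
    paste("seed =", model$seed),
    paste("n_epochs =", as.integer(n_epochs)),
    paste("artifact_rate =", model$artifact_rate),
    paste("sample_rate_hz = 256"),
    paste("stationary =", paste(round(stationary_distribution(model$transition), 4),
                                collapse = "/")),
    paste("wake_band =", paste(params$W$eeg_band, collapse = "-")),
    paste("nrem_band =", paste(params$N$eeg_band, collapse = "-")),
    paste("rem_band =", paste(params$R$eeg_band, collapse = "-")),
    paste("emg_rms =", paste(params$W$emg_rms, params$N$emg_rms,
                             params$R$emg_rms, sep = "/"))
  ), manifest_path)
  invisible(list(signal_path = signal_path, label_path = label_path,
                 manifest_path = manifest_path, stages = as.character(stages)))
}

#' Synthesize an in-memory epoch set for a given stage sequence
#'
#' Convenience generator used by tests and by [synthesize_recording()]: each
#' epoch gets an independent seed derived reproducibly from `seed`.
#'
#' @param stages Character vector of stage codes.
#' @param params A [stage_signal_params()].
#' @param seed Integer master seed.
#' @return An `epoch_set` (1024 samples per channel at 256 Hz).
#' @export
synthesize_epoch_set <- function(stages, params = stage_signal_params(),
                                 seed = 1L) {
  n <- length(stages)
  seeds <- .with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  eeg <- matrix(NA_real_, n, 1024L)
  emg <- matrix(NA_real_, n, 1024L)
  for (i in seq_len(n)) {
    ep <- synthesize_epoch(stages[i], params, seed = seeds[i])
    eeg[i, ] <- ep$eeg
    emg[i, ] <- ep$emg
  }
  structure(list(eeg = eeg, emg = emg, labels = as.character(stages),
                 sample_rate_hz = 256, source_id = "synthetic"),
            class = "epoch_set")
}

#' Fit the naive threshold baseline classifier
#'
#' A two-rule reference classifier that any learned model must beat: epochs
#' with log EMG RMS above a threshold are Wake; the remainder are NREM when
#' the EEG delta/theta log power ratio exceeds a second threshold, else REM.
#' Thresholds are the midpoints between class-conditional feature means on
#' the training labels. Its accuracy on default synthetic data certifies that
#' the learning task is solvable.
#'
#' @param data An `epoch_dataset` with known stages.
#' @return An object of class `baseline_classifier`.
#' @export
fit_baseline_classifier <- function(data) {
  stopifnot(inherits(data, "epoch_dataset"))
  f <- .baseline_features(data)
  st <- data$stages
  emg_thr <- mean(c(mean(f$log_emg_rms[st == "W"]),
                    mean(f$log_emg_rms[st != "W"])))
  sleep <- st != "W"
  dt_thr <- mean(c(mean(f$log_delta_theta[sleep & st == "N"]),
                   mean(f$log_delta_theta[sleep & st == "R"])))
  structure(list(emg_thr = emg_thr, dt_thr = dt_thr),
            class = "baseline_classifier")
}

#' @rdname fit_baseline_classifier
#' @param object A fitted `baseline_classifier`.
#' @param newdata An `epoch_dataset`.
#' @param ... Unused.
#' @return Character vector of predicted stage codes.
#' @export
predict.baseline_classifier <- function(object, newdata, ...) {
  f <- .baseline_features(newdata)
  ifelse(f$log_emg_rms > object$emg_thr, "W",
         ifelse(f$log_delta_theta > object$dt_thr, "N", "R"))
}

.baseline_features <- function(data) {
  n <- dim(data$signals)[1L]
  log_emg_rms <- numeric(n)
  log_dt <- numeric(n)
  for (i in seq_len(n)) {
    emg <- data$signals[i, , 2L]
    eeg <- data$signals[i, , 1L]
    log_emg_rms[i] <- log(sqrt(mean(emg^2)) + 1e-12)
    psd <- welch_psd(eeg, fs = data$epoch_rate_hz, nperseg = 128L)
    log_dt[i] <- log((band_power(psd, 0.5, 4) + 1e-12) /
                       (band_power(psd, 5, 9) + 1e-12))
  }
  list(log_emg_rms = log_emg_rms, log_delta_theta = log_dt)
}
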