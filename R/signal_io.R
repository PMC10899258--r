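#' Construct a raw EEG/EMG recording
#'
#' A raw recording holds two equal-length voltage series (in microvolts) for
#' the EEG and EMG channels, together with their common sampling rate.
#'
#' @param eeg Numeric vector of EEG voltages (uV).
#' @param emg Numeric vector of EMG voltages (uV), same length as `eeg`.
#' @param sample_rate_hz Positive sampling rate in Hz.
#' @param source_id Character tag identifying the recording's origin.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(eeg, emg, sample_rate_hz, source_id = "memory") {
  eeg <- as.numeric(eeg)
  emg <- as.numeric(emg)
  if (length(eeg) != length(emg)) {
    stop("EEG and EMG series must have identical length (got ",
         length(eeg), " and ", length(emg), ")")
  }
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      !is.finite(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("sample_rate_hz must be a single positive number")
  }
  if (anyNA(eeg) || anyNA(emg) || !all(is.finite(eeg)) || !all(is.finite(emg))) {
    stop("all voltage samples must be finite")
  }
  structure(
    list(eeg = eeg, emg = emg,
         sample_rate_hz = as.numeric(sample_rate_hz),
         source_id = as.character(source_id)),
    class = "raw_recording"
  )
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %s: %d samples @ %g Hz (%.1f s)\n",
              x$source_id, length(x$eeg), x$sample_rate_hz,
              length(x$eeg) / x$sample_rate_hz))
  invisible(x)
}

#' Read a two-column voltage table
#'
#' Reads a delimited text file whose rows are paired EEG and EMG voltages.
#' The delimiter (comma or tab) is autodetected and a single non-numeric
#' header line is skipped if present. Files that do not conform to the
#' two-float-column contract are rejected with an error naming the offending
#' line, mirroring the intake rule that non-conforming exports are excluded
#' from analysis.
#'
#' @param path Path to the file.
#' @param sample_rate_hz Sampling rate of the stored series (declared by the
#'   caller; the format carries no rate metadata).
#' @param source_id Optional identifier; defaults to the file name.
#' @return A [raw_recording()].
#' @export
read_voltage_table <- function(path, sample_rate_hz, source_id = NULL) {
  if (!file.exists(path)) stop("voltage file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("voltage file is empty: ", path)

  sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  split_row <- function(line) trimws(strsplit(line, sep, fixed = TRUE)[[1L]])

  first <- split_row(lines[[1L]])
  start <- 1L
  if (any(is.na(suppressWarnings(as.numeric(first))))) {
    # single header line permitted
    start <- 2L
    if (length(lines) < 2L) stop("voltage file has a header but no data: ", path)
  }

  n <- length(lines) - start + 1L
  eeg <- numeric(n)
  emg <- numeric(n)
  for (i in seq_len(n)) {
    fields <- split_row(lines[[start + i - 1L]])
    if (length(fields) != 2L) {
      stop("format rejection: line ", start + i - 1L, " of ", path,
           " has ", length(fields), " value columns (expected 2)")
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals)) {
      stop("format rejection: non-numeric cell on line ", start + i - 1L,
           " of ", path, ": '", paste(fields, collapse = sep), "'")
    }
    eeg[i] <- vals[1L]
    emg[i] <- vals[2L]
  }
  if (is.null(source_id)) source_id <- basename(path)
  raw_recording(eeg, emg, sample_rate_hz, source_id)
}

#' Write a recording as a two-column voltage table
#'
#' Full double precision is retained so that write/read round trips are exact.
#'
#' @param rec A [raw_recording()].
#' @param path Output file path.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @param header Write an `eeg,emg` header line (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_voltage_table <- function(rec, path, sep = ",", header = TRUE) {
  stopifnot(inherits(rec, "raw_recording"))
  body <- paste(format(rec$eeg, digits = 17, trim = TRUE, scientific = FALSE),
                format(rec$emg, digits = 17, trim = TRUE, scientific = FALSE),
                sep = sep)
  if (header) body <- c(paste("eeg", "emg", sep = sep), body)
  writeLines(body, path)
  invisible(path)
}

#' Stage label one-hot encoding
#'
#' Maps stage codes to the fixed one-hot scheme W = (1,0,0), N = (0,1,0),
#' R = (0,0,1); artifact epochs (A) are flagged as (1,1,1) and must be removed
#' before training.
#'
#' @param stages Character vector of codes in `{W, N, R, A}`.
#' @return Integer matrix of dimension `length(stages) x 3`,
#'   columns `W`, `N`, `R`.
#' @export
stage_onehot <- function(stages) {
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), c("W", "N", "R", "A"))
  if (length(bad) > 0L) {
    stop("unknown stage code(s): ", paste(bad, collapse = ", "))
  }
  map <- rbind(W = c(1L, 0L, 0L),
               N = c(0L, 1L, 0L),
               R = c(0L, 0L, 1L),
               A = c(1L, 1L, 1L))
  out <- map[stages, , drop = FALSE]
  dimnames(out) <- list(NULL, c("W", "N", "R"))
  out
}

#' Decode one-hot rows back to stage codes
#'
#' @param onehot Matrix with 3 columns (W, N, R); rows of all ones decode to
#'   the artifact code `A`.
#' @return Character vector of stage codes.
#' @export
onehot_to_stage <- function(onehot) {
  onehot <- as.matrix(onehot)
  stopifnot(ncol(onehot) == 3L)
  apply(onehot, 1L, function(r) {
    if (all(r == 1)) return("A")
    c("W", "N", "R")[which.max(r)]
  })
}

#' Parse a per-epoch stage label file
#'
#' One label per non-empty line; the first whitespace-separated token of each
#' line is taken. Tokens `W`, `N`, `R` are kept; every other token is treated
#' as an artifact and recoded `A`.
#'
#' @param path Path to the label file.
#' @return Character vector of stage codes in `{W, N, R, A}` (possibly empty).
#' @export
parse_stage_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(character(0))
  tokens <- vapply(strsplit(trimws(lines), "[[:space:]]+"), `[[`, "", 1L)
  ifelse(tokens %in% c("W", "N", "R"), tokens, "A")
}

#' Polyphase rational-ratio resampling
#'
#' Resamples a series by the rational factor `p/q` with an anti-aliasing FIR
#' low-pass: a Kaiser-windowed sinc of half-length `half_window * max(p, q)`
#' taps (after reducing `p/q` to lowest terms), applied by upsample-filter-
#' downsample. With `normalize_branches = TRUE` each polyphase branch is
#' rescaled to unit DC gain so constant signals are reproduced exactly away
#' from the edges.
#'
#' @param x Numeric series.
#' @param p,q Positive integers; output rate is `p/q` times the input rate.
#' @param half_window Filter half-length in output-period units (default 10).
#' @param kaiser_beta Kaiser window shape parameter (default 5).
#' @param normalize_branches Normalize per-branch DC gain (default `TRUE`).
#' @return Numeric series of length `ceiling(length(x) * p / q)`.
#' @export
resample_polyphase <- function(x, p, q, half_window = 10L, kaiser_beta = 5,
                               normalize_branches = TRUE) {
  stopifnot(length(p) == 1L, length(q) == 1L, p >= 1, q >= 1)
  if (abs(p - round(p)) > 1e-9 || abs(q - round(q)) > 1e-9) {
    stop("resampling ratio must be expressible with integer p and q")
  }
  p <- as.integer(round(p)); q <- as.integer(round(q))
  g <- .gcd(p, q); p <- p %/% g; q <- q %/% g
  if (p == 1L && q == 1L) return(as.numeric(x))

  x <- as.numeric(x)
  nx <- length(x)
  max_rate <- max(p, q)
  f_c <- 1 / (2 * max_rate)
  half_len <- as.integer(half_window) * max_rate
  m <- (-half_len):half_len
  h <- 2 * f_c * .sinc(2 * f_c * m) * signal::kaiser(2L * half_len + 1L, kaiser_beta)
  h <- p * h / sum(h)
  if (normalize_branches && p > 1L) {
    branch <- (seq_along(h) - 1L) %% p
    for (b in 0:(p - 1L)) {
      idx <- which(branch == b)
      h[idx] <- h[idx] / sum(h[idx])
    }
  } else if (normalize_branches && p == 1L) {
    h <- h / sum(h)
  }

  xu <- numeric(nx * p)
  xu[seq.int(1L, nx * p, by = p)] <- x
  yf <- stats::convolve(xu, rev(h), type = "open")
  y <- yf[(half_len + 1L):(half_len + nx * p)]
  y[seq.int(1L, nx * p, by = q)]
}

.sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

.gcd <- function(a, b) if (b == 0L) a else .gcd(b, a %% b)

#' Resample a recording to a lower rate
#'
#' Both channels are resampled by the rational ratio `target_hz /
#' sample_rate_hz` (e.g. 500 Hz telemetry exports to the 256 Hz scoring rate
#' use 64/125) with the polyphase anti-aliased resampler.
#'
#' @param rec A [raw_recording()].
#' @param target_hz Target rate; must not exceed the current rate and the
#'   ratio must be expressible as a rational number with denominator up to
#'   1000.
#' @return A [raw_recording()] at `target_hz`.
#' @export
resample_recording <- function(rec, target_hz) {
  stopifnot(inherits(rec, "raw_recording"))
  if (target_hz > rec$sample_rate_hz) {
    stop("target_hz (", target_hz, ") exceeds the recording rate (",
         rec$sample_rate_hz, ")")
  }
  if (target_hz == rec$sample_rate_hz) return(rec)
  frac <- .as_fraction(target_hz / rec$sample_rate_hz, max_den = 1000L)
  if (is.null(frac)) {
    stop("resampling ratio ", target_hz, "/", rec$sample_rate_hz,
         " is not expressible as a small rational number")
  }
  raw_recording(
    eeg = resample_polyphase(rec$eeg, frac[1L], frac[2L]),
    emg = resample_polyphase(rec$emg, frac[1L], frac[2L]),
    sample_rate_hz = target_hz,
    source_id = rec$source_id
  )
}

# continued-fraction rational approximation; NULL when no denominator
# <= max_den reproduces `x` to 1e-9 relative tolerance
.as_fraction <- function(x, max_den = 1000L, tol = 1e-9) {
  for (den in seq_len(max_den)) {
    num <- round(x * den)
    if (num >= 1 && abs(num / den - x) <= tol * x) {
      return(c(as.integer(num), as.integer(den)))
    }
  }
  NULL
}

#' Segment a 256 Hz recording into labelled 4-s epochs
#'
#' Epoch `i` (1-based) covers samples `(1024 * (i - 1) + 1) : (1024 * i)`,
#' i.e. 0-based half-open windows of 1024 samples. A trailing partial window
#' is dropped. The number of epochs is the smaller of the sample-derived
#' count and the label count; if the two disagree by more than one epoch the
#' recording and score file are considered misaligned and an error reports
#' both counts. With `labels = NULL` (inference on unscored data) all
#' complete windows are segmented and labels are set to `NA`.
#'
#' @param rec A [raw_recording()] sampled at 256 Hz.
#' @param labels Character vector of per-epoch stage codes, or `NULL`.
#' @return An object of class `epoch_set`: matrices `eeg` and `emg` of
#'   dimension `n_epochs x 1024`, a `labels` character vector, the sampling
#'   rate and the source id.
#' @export
segment_into_epochs <- function(rec, labels = NULL) {
  stopifnot(inherits(rec, "raw_recording"))
  if (rec$sample_rate_hz != 256) {
    stop("epoching expects a 256 Hz recording; resample first (got ",
         rec$sample_rate_hz, " Hz)")
  }
  spe <- 1024L  # 4 s x 256 Hz
  n_sig <- length(rec$eeg) %/% spe
  if (n_sig < 1L) stop("recording shorter than one 4-s epoch")
  if (is.null(labels)) {
    n <- n_sig
    labels <- rep(NA_character_, n)
  } else {
    labels <- as.character(labels)
    if (length(labels) == 0L) stop("labels must be non-empty")
    if (abs(n_sig - length(labels)) > 1L) {
      stop("alignment error: recording yields ", n_sig,
           " complete epochs but the score file has ", length(labels),
           " labels")
    }
    n <- min(n_sig, length(labels))
    labels <- labels[seq_len(n)]
  }
  idx <- seq_len(n * spe)
  structure(
    list(
      eeg = matrix(rec$eeg[idx], nrow = n, ncol = spe, byrow = TRUE),
      emg = matrix(rec$emg[idx], nrow = n, ncol = spe, byrow = TRUE),
      labels = labels,
      sample_rate_hz = 256,
      source_id = rec$source_id
    ),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c("W", "N", "R", "A")))
  cat(sprintf("<epoch_set> %s: %d epochs x %d samples @ %g Hz\n",
              x$source_id, nrow(x$eeg), ncol(x$eeg), x$sample_rate_hz))
  cat("  labels:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}
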