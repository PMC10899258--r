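#' Score a recording into a hypnogram
#'
#' Runs the full inference chain on a raw recording: read (when given a
#' path), resample to 256 Hz if needed, segment into 4-s epochs, preprocess
#' (never augmented), forward through the network, and take the argmax stage
#' per epoch. Ties are broken toward the earlier class in (W, N, R) order, so
#' scoring is fully deterministic and independent of the inference batch
#' size.
#'
#' @param model A trained `resnet_model`.
#' @param recording A [raw_recording()] or a path to a voltage table.
#' @param sample_rate_hz Sampling rate when `recording` is a path
#'   (default 256).
#' @param batch_size Inference batch size.
#' @return An object of class `hypnogram`: data.frame with columns
#'   `epoch_index` (1-based), `start_s`, `stage`, `p_wake`, `p_nrem`,
#'   `p_rem`.
#' @export
score_recording <- function(model, recording, sample_rate_hz = 256,
                            batch_size = 128L) {
  stopifnot(inherits(model, "resnet_model"))
  if (is.character(recording)) {
    recording <- read_voltage_table(recording, sample_rate_hz)
  }
  stopifnot(inherits(recording, "raw_recording"))
  if (recording$sample_rate_hz != 256) {
    recording <- resample_recording(recording, 256)
  }
  epochs <- segment_into_epochs(recording, labels = NULL)
  data <- preprocess_dataset(epochs)
  probs <- predict_stages(model, data, batch_size = batch_size)
  .hypnogram_from_probs(probs)
}

#' Score a preprocessed dataset into a hypnogram
#'
#' @param model A trained `resnet_model`.
#' @param data An `epoch_dataset`.
#' @param batch_size Inference batch size.
#' @return A `hypnogram` (see [score_recording()]).
#' @export
score_dataset <- function(model, data, batch_size = 128L) {
  probs <- predict_stages(model, data, batch_size = batch_size)
  .hypnogram_from_probs(probs)
}

.hypnogram_from_probs <- function(probs) {
  n <- nrow(probs)
  # max.col("first") = earliest class in (W, N, R) order on exact ties
  stage <- c("W", "N", "R")[max.col(probs, ties.method = "first")]
  structure(
    data.frame(epoch_index = seq_len(n),
               start_s = (seq_len(n) - 1) * 4,
               stage = stage,
               p_wake = probs[, "W"],
               p_nrem = probs[, "N"],
               p_rem = probs[, "R"]),
    class = c("hypnogram", "data.frame")
  )
}

#' Build a hypnogram from known stage labels
#'
#' Utility for comparing manual scores against predictions: wraps a W/N/R
#' label sequence as a degenerate (probability 1) hypnogram on the 4-s grid.
#'
#' @param stages Character vector of codes in `{W, N, R}`.
#' @return A `hypnogram`.
#' @export
hypnogram_from_stages <- function(stages) {
  stages <- as.character(stages)
  stopifnot(all(stages %in% c("W", "N", "R")))
  probs <- stage_onehot(stages)
  colnames(probs) <- c("W", "N", "R")
  .hypnogram_from_probs(probs)
}

#' @export
plot.hypnogram <- function(x, ...) {
  lev <- c(R = 1, N = 2, W = 3)
  graphics::plot(x$start_s / 3600, lev[x$stage], type = "s", yaxt = "n",
                 xlab = "time (h)", ylab = "", ylim = c(0.5, 3.5), ...)
  graphics::axis(2, at = 1:3, labels = c("REM", "NREM", "Wake"), las = 1)
  invisible(x)
}

#' Bin a hypnogram into stage minutes per window
#'
#' Counts the minutes spent in each stage per `bin_hours` window (a full 2-h
#' bin holds 1800 4-s epochs, so its stage minutes sum to 120). A trailing
#' partial bin is reported with its actual duration and flagged
#' `complete = FALSE`.
#'
#' @param h A `hypnogram`.
#' @param bin_hours Bin width in hours (default 2).
#' @return An object of class `binned_stages`: data.frame with columns
#'   `bin_start_h`, `wake_min`, `nrem_min`, `rem_min`, `complete`.
#' @export
bin_hypnogram <- function(h, bin_hours = 2) {
  stopifnot(inherits(h, "hypnogram"), nrow(h) > 0)
  per_bin <- as.integer(round(bin_hours * 3600 / 4))
  bin <- (h$epoch_index - 1L) %/% per_bin
  out <- do.call(rbind, lapply(split(seq_len(nrow(h)), bin), function(idx) {
    st <- h$stage[idx]
    data.frame(
      bin_start_h = (bin[idx[1L]]) * bin_hours,
      wake_min = sum(st == "W") * 4 / 60,
      nrem_min = sum(st == "N") * 4 / 60,
      rem_min = sum(st == "R") * 4 / 60,
      complete = length(idx) == per_bin
    )
  }))
  rownames(out) <- NULL
  class(out) <- c("binned_stages", class(out))
  out
}

#' Concordance between manual and predicted stage minutes
#'
#' Pearson correlation between true and predicted minutes-per-bin, per stage
#' and pooled over the three stages. Partial trailing bins are excluded by
#' default. Zero-variance series yield `NA` with a warning rather than an
#' error.
#'
#' @param true_bins,pred_bins `binned_stages` tables on the same bin grid.
#' @param full_bins_only Exclude incomplete bins (default `TRUE`).
#' @return A data.frame with columns `stage` (`wake`, `nrem`, `rem`,
#'   `pooled`), `r`, `p_value`, `n_bins`.
#' @export
concordance <- function(true_bins, pred_bins, full_bins_only = TRUE) {
  stopifnot(inherits(true_bins, "binned_stages"),
            inherits(pred_bins, "binned_stages"))
  if (nrow(true_bins) != nrow(pred_bins) ||
      any(true_bins$bin_start_h != pred_bins$bin_start_h)) {
    stop("bin grids do not match")
  }
  keep <- if (full_bins_only) true_bins$complete & pred_bins$complete else
    rep(TRUE, nrow(true_bins))
  if (sum(keep) < 3L) {
    stop("need at least 3 bins for a correlation; got ", sum(keep),
         if (full_bins_only) " complete bins (set full_bins_only = FALSE?)")
  }
  cols <- c(wake = "wake_min", nrem = "nrem_min", rem = "rem_min")
  one <- function(y, yhat, label) {
    if (stats::sd(y) == 0 || stats::sd(yhat) == 0) {
      warning("zero variance in ", label, " minutes; r undefined")
      return(data.frame(stage = label, r = NA_real_, p_value = NA_real_,
                        n_bins = length(y)))
    }
    ct <- stats::cor.test(y, yhat)
    data.frame(stage = label, r = unname(ct$estimate),
               p_value = ct$p.value, n_bins = length(y))
  }
  res <- do.call(rbind, lapply(names(cols), function(s) {
    one(true_bins[[cols[s]]][keep], pred_bins[[cols[s]]][keep], s)
  }))
  pooled <- one(unlist(lapply(cols, function(cc) true_bins[[cc]][keep]),
                       use.names = FALSE),
                unlist(lapply(cols, function(cc) pred_bins[[cc]][keep]),
                       use.names = FALSE),
                "pooled")
  rbind(res, pooled)
}
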