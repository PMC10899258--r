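#' Augmentation configuration
#'
#' Training-time stochastic transforms applied per epoch, in the order
#' amplitude scaling, joint translation, additive noise. The published
#' protocol names the three transforms but not their magnitudes; the defaults
#' here are conservative: independent per-channel amplitude factors drawn
#' uniformly from `[0.8, 1.2]`, a single circular time shift of up to 64 of
#' the 256 samples applied identically to both channels (temporal yoking),
#' and Gaussian noise at 5% of each channel's per-epoch standard deviation.
#' Validation data are never augmented.
#'
#' @param amp_scale_range Length-2 positive interval for amplitude factors.
#' @param max_shift Maximum circular shift in samples, `0 <= max_shift < 256`.
#' @param noise_sigma Noise SD as a fraction of per-epoch channel SD.
#' @param seed Integer seed for the augmentation stream.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(amp_scale_range = c(0.8, 1.2),
                           max_shift = 64L,
                           noise_sigma = 0.05,
                           seed = 1L) {
  if (length(amp_scale_range) != 2L || any(amp_scale_range <= 0) ||
      amp_scale_range[1L] > amp_scale_range[2L]) {
    stop("amp_scale_range must be a positive, ordered interval")
  }
  if (max_shift < 0 || max_shift >= 256) stop("max_shift must be in [0, 256)")
  if (noise_sigma < 0) stop("noise_sigma must be nonnegative")
  structure(list(amp_scale_range = as.numeric(amp_scale_range),
                 max_shift = as.integer(max_shift),
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "augment_config")
}

#' Independent per-channel amplitude scaling
#'
#' Each channel is multiplied by its own factor drawn uniformly from
#' `amp_scale_range`; EEG and EMG draws are independent. Uses the current RNG
#' stream.
#'
#' @param epoch Numeric matrix `(256, 2)`.
#' @param amp_scale_range Length-2 interval.
#' @return The scaled epoch.
#' @export
scale_amplitude <- function(epoch, amp_scale_range = c(0.8, 1.2)) {
  factors <- stats::runif(2L, amp_scale_range[1L], amp_scale_range[2L])
  epoch * rep(factors, each = nrow(epoch))
}

#' Temporally yoked circular translation
#'
#' One shift `s` is drawn uniformly from `[-max_shift, max_shift]` and both
#' channels are rolled circularly by the same amount, preserving the EEG/EMG
#' temporal alignment and the signal energy.
#'
#' @param epoch Numeric matrix `(256, 2)`.
#' @param max_shift Maximum absolute shift in samples.
#' @param shift Optional fixed shift (bypasses the random draw).
#' @return The translated epoch.
#' @export
translate_jointly <- function(epoch, max_shift = 64L, shift = NULL) {
  n <- nrow(epoch)
  if (is.null(shift)) {
    shift <- sample.int(2L * max_shift + 1L, 1L) - max_shift - 1L
  }
  s <- ((shift %% n) + n) %% n
  if (s == 0L) return(epoch)
  epoch[c((n - s + 1L):n, 1L:(n - s)), , drop = FALSE]
}

#' Additive Gaussian noise
#'
#' Adds zero-mean Gaussian noise with per-channel SD equal to `noise_sigma`
#' times that channel's per-epoch SD.
#'
#' @param epoch Numeric matrix `(256, 2)`.
#' @param noise_sigma Fractional noise SD.
#' @return The noisy epoch.
#' @export
add_noise <- function(epoch, noise_sigma = 0.05) {
  if (noise_sigma <= 0) return(epoch)
  n <- nrow(epoch)
  sds <- apply(epoch, 2L, stats::sd) * noise_sigma
  epoch + cbind(stats::rnorm(n, sd = sds[1L]), stats::rnorm(n, sd = sds[2L]))
}

#' Augment a batch (training only)
#'
#' With `training = TRUE`, applies scale, then translation, then noise to
#' each epoch with fresh draws; with `training = FALSE` the batch passes
#' through bit-identically. Labels are never altered.
#'
#' @param batch Numeric array `(B, 256, 2)`.
#' @param labels Label matrix `(B, 3)` (returned unchanged).
#' @param cfg An [augment_config()].
#' @param training Logical.
#' @return List with `batch` and `labels`.
#' @export
augment_batch <- function(batch, labels, cfg = augment_config(),
                          training = TRUE) {
  if (!training) return(list(batch = batch, labels = labels))
  B <- dim(batch)[1L]
  for (i in seq_len(B)) {
    ep <- batch[i, , ]
    ep <- scale_amplitude(ep, cfg$amp_scale_range)
    ep <- translate_jointly(ep, cfg$max_shift)
    ep <- add_noise(ep, cfg$noise_sigma)
    batch[i, , ] <- ep
  }
  list(batch = batch, labels = labels)
}
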