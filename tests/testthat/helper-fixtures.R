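# shared fixtures, built in code at test time

# memoised small synthetic dataset so several test files can reuse one build
.fixture_cache <- new.env(parent = emptyenv())

tiny_dataset <- function(n = 300L, seed = 7L, artifact_rate = 0.02) {
  key <- paste("ds", n, seed, artifact_rate, sep = "_")
  if (is.null(.fixture_cache[[key]])) {
    stages <- sample_stage_sequence(
      n, transition_model(artifact_rate = artifact_rate, seed = seed))
    epochs <- synthesize_epoch_set(stages, seed = seed)
    .fixture_cache[[key]] <- suppressMessages(preprocess_dataset(epochs))
  }
  .fixture_cache[[key]]
}

# least-squares amplitude of a sinusoid at a known frequency
fit_sine_amplitude <- function(x, freq, fs) {
  t <- (seq_along(x) - 1) / fs
  a <- cbind(sin(2 * pi * freq * t), cos(2 * pi * freq * t))
  co <- qr.solve(a, x)
  sqrt(sum(co^2))
}

# brute-force per-class counts, independent of the package implementation
brute_force_ovr <- function(true, pred, stage) {
  tp <- sum(true == stage & pred == stage)
  fp <- sum(true != stage & pred == stage)
  fn <- sum(true == stage & pred != stage)
  tn <- sum(true != stage & pred != stage)
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}
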