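#' Stratified k-fold splits
#'
#' Shuffles the indices of each stage separately under `seed` and deals them
#' round-robin into `k` folds, so every fold's per-class count is within one
#' sample of `n_class / k`. Fold `i`'s test set is fold `i`; its training set
#' is the union of the others (an 80/20 partition at `k = 5`), preserving the
#' global class proportions on both sides.
#'
#' @param labels One-hot matrix `(N, 3)` or character vector of stage codes.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return List of `k` splits, each a list with `fold_id`, `train_idx`,
#'   `test_idx`.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L) {
  stages <- if (is.matrix(labels)) onehot_to_stage(labels) else as.character(labels)
  k <- as.integer(k)
  counts <- table(stages)
  if (any(counts < k)) {
    stop("every class needs at least k = ", k, " members; got ",
         paste(names(counts), counts, sep = "=", collapse = ", "))
  }
  fold_of <- integer(length(stages))
  .with_seed(seed, {
    for (s in unique(stages)) {
      idx <- sample(which(stages == s))
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  lapply(seq_len(k), function(i) {
    list(fold_id = i,
         train_idx = which(fold_of != i),
         test_idx = which(fold_of == i))
  })
}

# core optimization loop. x: (N, 256, 2); y: (N, 3). Returns a train_history
# data.frame with attributes "best_state" (parameters at the lowest monitored
# training loss), "final_state", and "train_indices_used".
.train_loop <- function(model, x, y, x_val, y_val, cfg, aug = NULL,
                        shuffle_seed = cfg$seed) {
  n <- dim(x)[1L]
  lr <- cfg$learning_rate
  best_loss <- Inf
  best_state <- NULL
  plateau <- 0L
  hist <- vector("list", cfg$num_epochs)
  used <- logical(n)

  .with_seed(shuffle_seed + 1L, {
    for (ep in seq_len(cfg$num_epochs)) {
      ord <- sample.int(n)             # temporal order randomized each pass
      ep_loss <- 0
      ep_correct <- 0L
      for (start in seq.int(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        used[idx] <- TRUE
        xb <- x[idx, , , drop = FALSE]
        yb <- y[idx, , drop = FALSE]
        if (!is.null(aug)) {
          ab <- augment_batch(xb, yb, aug, training = TRUE)
          xb <- ab$batch
        }
        probs <- .model_forward(model, xb, training = TRUE)
        loss <- .model_backward(model, probs, yb)
        if (!is.finite(loss)) {
          stop("training diverged: non-finite loss at training epoch ", ep,
               " (lr = ", lr, ")")
        }
        .adam_step(model, lr)
        ep_loss <- ep_loss + loss * length(idx)
        ep_correct <- ep_correct +
          sum(max.col(probs) == max.col(yb))
      }
      train_loss <- ep_loss / n
      train_acc <- ep_correct / n

      val_loss <- NA_real_
      val_acc <- NA_real_
      if (!is.null(x_val)) {
        vp <- .predict_probs(model, x_val, batch_size = cfg$batch_size)
        val_loss <- categorical_cross_entropy(y_val, vp)
        val_acc <- mean(max.col(vp) == max.col(y_val))
      }
      hist[[ep]] <- data.frame(epoch = ep, lr = lr,
                               train_loss = train_loss, train_acc = train_acc,
                               val_loss = val_loss, val_acc = val_acc)

      # checkpoint + plateau schedule, both monitoring the training loss
      if (train_loss < best_loss - 1e-12) {
        best_loss <- train_loss
        best_state <- .model_state(model)
        plateau <- 0L
      } else {
        plateau <- plateau + 1L
        if (plateau >= cfg$lr_reduce_patience) {
          lr <- max(lr * cfg$lr_reduce_factor, cfg$lr_floor)
          plateau <- 0L
        }
      }
    }
  })
  history <- do.call(rbind, hist)
  class(history) <- c("train_history", class(history))
  attr(history, "best_state") <- best_state
  attr(history, "best_loss") <- best_loss
  attr(history, "final_state") <- .model_state(model)
  attr(history, "train_indices_used") <- which(used)
  history
}

# batched deterministic inference; x: (N, 256, 2) -> (N, 3)
.predict_probs <- function(model, x, batch_size = 128L) {
  n <- dim(x)[1L]
  out <- matrix(NA_real_, n, 3L, dimnames = list(NULL, c("W", "N", "R")))
  for (start in seq.int(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    out[idx, ] <- .model_forward(model, x[idx, , , drop = FALSE],
                                 training = FALSE)
  }
  out
}

#' Predict stage probabilities for a preprocessed dataset
#'
#' @param model A trained `resnet_model`.
#' @param data An `epoch_dataset` or a `(N, 256, 2)` array.
#' @param batch_size Inference batch size (the result is independent of it).
#' @return Probability matrix `(N, 3)`, columns W/N/R.
#' @export
predict_stages <- function(model, data, batch_size = 128L) {
  x <- if (inherits(data, "epoch_dataset")) data$signals else data
  .predict_probs(model, x, batch_size = batch_size)
}

#' Train on one cross-validation fold
#'
#' Trains a fresh network on the split's training side with the published
#' protocol: Adam, categorical cross-entropy, minibatches of
#' `cfg$batch_size`, up to `cfg$num_epochs` passes with the training epochs
#' reshuffled each pass, augmentation applied to training batches only, the
#' best parameters checkpointed by training loss, and the learning rate
#' halved whenever the training loss fails to improve for
#' `cfg$lr_reduce_patience` consecutive passes.
#'
#' @param data An `epoch_dataset` with labels.
#' @param split One element of [stratified_kfold()].
#' @param cfg A [model_config()].
#' @param aug An [augment_config()] or `NULL` to disable augmentation.
#' @param restore Which checkpoint the returned model carries: `"best"`
#'   (lowest monitored loss, default) or `"final"`.
#' @return List with `model` (a `resnet_model`) and `history` (a
#'   `train_history` data.frame: per-pass learning rate, train/validation
#'   loss and accuracy).
#' @export
train_fold <- function(data, split, cfg = model_config(), aug = NULL,
                       restore = c("best", "final")) {
  stopifnot(inherits(data, "epoch_dataset"))
  restore <- match.arg(restore)
  model <- build_model(cfg)
  x <- data$signals
  y <- data$labels
  history <- .train_loop(model,
                         x[split$train_idx, , , drop = FALSE],
                         y[split$train_idx, , drop = FALSE],
                         x[split$test_idx, , , drop = FALSE],
                         y[split$test_idx, , drop = FALSE],
                         cfg, aug,
                         shuffle_seed = cfg$seed + split$fold_id)
  st <- if (restore == "best") attr(history, "best_state") else
    attr(history, "final_state")
  .model_restore(model, st)
  list(model = model, history = history)
}

#' @export
plot.train_history <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(x$epoch, cbind(x$train_loss, x$val_loss), type = "l",
                    lty = 1, col = c("black", "red"),
                    xlab = "training epoch", ylab = "loss", main = "loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "red"), bty = "n")
  graphics::matplot(x$epoch, cbind(x$train_acc, x$val_acc), type = "l",
                    lty = 1, col = c("black", "red"),
                    xlab = "training epoch", ylab = "accuracy",
                    main = "accuracy", ...)
  invisible(x)
}

#' Stratified k-fold cross-validation
#'
#' Trains one network per fold and evaluates it on the fold's held-out 20%.
#' The report mirrors the standard cross-validation table: per stage (W, N,
#' R) accuracy, precision, recall, F1 (percent) and one-vs-rest Cohen's
#' kappa, one row per fold plus mean and SEM rows.
#'
#' @param data An `epoch_dataset` with labels.
#' @param cfg A [model_config()].
#' @param aug An [augment_config()] or `NULL`.
#' @param k Number of folds (default 5).
#' @param seed Seed for the fold assignment.
#' @return An object of class `cv_result`: list with `metrics` (the
#'   k+2-row data.frame), `folds`, `histories` and `confusions`.
#' @export
cross_validate <- function(data, cfg = model_config(), aug = NULL, k = 5L,
                           seed = 1L) {
  stopifnot(inherits(data, "epoch_dataset"))
  folds <- stratified_kfold(data$labels, k = k, seed = seed)
  rows <- vector("list", k)
  histories <- vector("list", k)
  confusions <- vector("list", k)
  for (i in seq_len(k)) {
    fit <- train_fold(data, folds[[i]], cfg, aug)
    probs <- predict_stages(fit$model, data$signals[folds[[i]]$test_idx, , ,
                                                    drop = FALSE])
    pred <- c("W", "N", "R")[max.col(probs)]
    true <- onehot_to_stage(data$labels[folds[[i]]$test_idx, , drop = FALSE])
    cm <- confusion_matrix(true, pred)
    rows[[i]] <- cbind(data.frame(fold = i), stage_metrics_row(cm))
    histories[[i]] <- fit$history
    confusions[[i]] <- cm
  }
  per_fold <- do.call(rbind, rows)
  summ <- fold_summary(per_fold[, -1L])
  metrics <- rbind(
    cbind(data.frame(fold = as.character(per_fold$fold)), per_fold[, -1L]),
    cbind(data.frame(fold = c("mean", "sem")), summ)
  )
  rownames(metrics) <- NULL
  structure(list(metrics = metrics, folds = folds, histories = histories,
                 confusions = confusions),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> stratified", length(x$folds), "fold cross-validation\n")
  print(cbind(fold = x$metrics$fold,
              round(x$metrics[, -1L], 2)), row.names = FALSE)
  invisible(x)
}

#' Train the final model on the full dataset
#'
#' Uses an internal stratified 80/20 monitor split for the validation curve,
#' trains for the full `cfg$num_epochs` passes, and keeps the final-epoch
#' parameters (not the checkpointed best), matching the deployment protocol.
#' A manifest records the configuration, seeds and a dataset fingerprint.
#'
#' @param data An `epoch_dataset` with labels.
#' @param cfg A [model_config()].
#' @param aug An [augment_config()] or `NULL`.
#' @param monitor_frac Held-out fraction used only for monitoring
#'   (default 0.2).
#' @return List with `model`, `history` and `manifest` (named character
#'   vector).
#' @export
train_final <- function(data, cfg = model_config(), aug = NULL,
                        monitor_frac = 0.2) {
  stopifnot(inherits(data, "epoch_dataset"))
  k <- max(2L, as.integer(round(1 / monitor_frac)))
  split <- stratified_kfold(data$labels, k = k, seed = cfg$seed)[[1L]]
  fit <- train_fold(data, split, cfg, aug, restore = "final")
  manifest <- c(
    num_epochs = cfg$num_epochs, learning_rate = cfg$learning_rate,
    batch_size = cfg$batch_size, optimizer_name = cfg$optimizer_name,
    n_resnet_blocks = cfg$n_resnet_blocks,
    n_feature_maps = cfg$n_feature_maps, kernel_y = cfg$kernel_y,
    strides = paste(cfg$strides, collapse = "x"),
    dropout_rate = cfg$dropout_rate,
    seed = cfg$seed,
    augmentation = if (is.null(aug)) "none" else
      paste0("scale[", paste(aug$amp_scale_range, collapse = ","),
             "]+shift", aug$max_shift, "+noise", aug$noise_sigma),
    n_train_epochs_data = dim(data$signals)[1L],
    data_fingerprint = sprintf("%.10g", sum(data$signals) +
                                 sum(data$labels))
  )
  list(model = fit$model, history = fit$history,
       manifest = vapply(manifest, as.character, ""))
}
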