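#' Model configuration
#'
#' Collects the nine training hyperparameters together with the architecture
#' shape decisions. Defaults are the published values: 50 training epochs,
#' Adam at learning rate 1e-6, batch size 128, seven residual blocks starting
#' at 8 feature maps (doubling per block to 512), kernel extent 2, strides
#' (1,1), dropout 0. `kernel_axis` resolves the kernel-orientation ambiguity:
#' `"time"` (default) spans 2 steps along the time axis and 1 along the
#' channel axis; `"channel"` is the transposed reading.
#'
#' @param num_epochs Training epochs (passes over the training set).
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param optimizer_name Only `"Adam"` is implemented.
#' @param n_resnet_blocks Number of residual blocks.
#' @param n_feature_maps Feature maps in the first block; doubles per block.
#' @param kernel_y Kernel extent along the oriented axis (fixed 2).
#' @param kernel_axis `"time"` or `"channel"`.
#' @param strides Convolution strides; only `(1, 1)` is supported (required
#'   for the elementwise residual merge under "same" padding).
#' @param dropout_rate Dropout rate inside residual blocks (default 0; the
#'   layers are present but inert).
#' @param n_classes Number of output classes (3: W, N, R).
#' @param input_shape Input tensor shape per sample, `(256, 2, 1)`.
#' @param lr_reduce_factor,lr_reduce_patience,lr_floor Learning-rate-on-
#'   plateau schedule: multiply by `lr_reduce_factor` after
#'   `lr_reduce_patience` consecutive non-improving training epochs, never
#'   below `lr_floor`.
#' @param seed Integer seed for weight initialization and shuffling.
#' @return An object of class `model_config`.
#' @export
model_config <- function(num_epochs = 50L,
                         learning_rate = 1e-6,
                         batch_size = 128L,
                         optimizer_name = "Adam",
                         n_resnet_blocks = 7L,
                         n_feature_maps = 8L,
                         kernel_y = 2L,
                         kernel_axis = c("time", "channel"),
                         strides = c(1L, 1L),
                         dropout_rate = 0,
                         n_classes = 3L,
                         input_shape = c(256L, 2L, 1L),
                         lr_reduce_factor = 0.5,
                         lr_reduce_patience = 3L,
                         lr_floor = 1e-8,
                         seed = 1L) {
  kernel_axis <- match.arg(kernel_axis)
  if (optimizer_name != "Adam") stop("only the Adam optimizer is implemented")
  if (!identical(as.integer(strides), c(1L, 1L))) {
    stop("only strides (1,1) are supported")
  }
  if (kernel_y != 2L) stop("kernel extent is fixed at 2")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0,1)")
  if (n_resnet_blocks < 1L || n_feature_maps < 1L) stop("invalid block/map counts")
  structure(list(
    num_epochs = as.integer(num_epochs),
    learning_rate = learning_rate,
    batch_size = as.integer(batch_size),
    optimizer_name = optimizer_name,
    n_resnet_blocks = as.integer(n_resnet_blocks),
    n_feature_maps = as.integer(n_feature_maps),
    kernel_y = 2L,
    kernel_axis = kernel_axis,
    strides = c(1L, 1L),
    dropout_rate = dropout_rate,
    n_classes = as.integer(n_classes),
    input_shape = as.integer(input_shape),
    lr_reduce_factor = lr_reduce_factor,
    lr_reduce_patience = as.integer(lr_reduce_patience),
    lr_floor = lr_floor,
    seed = as.integer(seed)
  ), class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config>\n")
  for (nm in c("num_epochs", "learning_rate", "batch_size", "optimizer_name",
               "n_resnet_blocks", "n_feature_maps", "kernel_y", "strides",
               "dropout_rate")) {
    cat(sprintf("  %-16s %s\n", nm, paste(x[[nm]], collapse = ",")))
  }
  cat(sprintf("  %-16s (%s)\n", "input_shape",
              paste(x$input_shape, collapse = ", ")))
  invisible(x)
}

#' Build a single residual block
#'
#' Body: [conv (2,1) - batch norm - dropout - ReLU] twice, then a final
#' conv (2,1) - batch norm. Shortcut: identity when `in_maps == out_maps`,
#' else a 1x1 projection convolution with batch norm. Merge: elementwise add
#' followed by ReLU. All convolutions use stride (1,1) and "same" padding so
#' the time/channel extent never changes.
#'
#' @param in_maps,out_maps Input/output feature-map counts.
#' @param dropout_rate Dropout rate (0 disables).
#' @param kernel_axis `"time"` or `"channel"` kernel orientation.
#' @return A residual block (environment), as used inside [build_model()].
#' @export
build_block <- function(in_maps, out_maps, dropout_rate = 0,
                        kernel_axis = "time") {
  if (in_maps < 1L || out_maps < 1L) stop("map counts must be positive")
  .new_block(as.integer(in_maps), as.integer(out_maps),
             dropout_rate = dropout_rate, axis = kernel_axis)
}

#' Build the residual network
#'
#' Stacks `n_resnet_blocks` residual blocks whose widths start at
#' `n_feature_maps` and double per block (default 8, 16, 32, 64, 128, 256,
#' 512), followed by global average pooling over the time x channel extent
#' and a dense softmax layer with `n_classes` outputs. Convolution weights
#' use He initialization under the configuration seed; the final dense layer
#' is zero-initialized so a fresh model outputs exactly uniform class
#' probabilities.
#'
#' @param cfg A [model_config()].
#' @return An object of class `resnet_model`.
#' @export
build_model <- function(cfg = model_config()) {
  stopifnot(inherits(cfg, "model_config"))
  .with_seed(cfg$seed, {
    model <- new.env(parent = emptyenv())
    model$cfg <- cfg
    widths <- cfg$n_feature_maps * 2L^(seq_len(cfg$n_resnet_blocks) - 1L)
    in_maps <- 1L
    model$blocks <- vector("list", cfg$n_resnet_blocks)
    for (i in seq_len(cfg$n_resnet_blocks)) {
      model$blocks[[i]] <- .new_block(in_maps, widths[i],
                                      dropout_rate = cfg$dropout_rate,
                                      axis = cfg$kernel_axis)
      in_maps <- widths[i]
    }
    model$widths <- widths
    model$dense <- .new_dense(in_maps, cfg$n_classes)
    .adam_init(model)
    class(model) <- c("resnet_model", "environment")
    model
  })
}

#' @export
print.resnet_model <- function(x, ...) {
  cat(sprintf("<resnet_model> %d residual blocks (widths %s), %d classes, %s parameters\n",
              length(x$blocks), paste(x$widths, collapse = "-"),
              x$cfg$n_classes,
              format(count_trainable_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Forward pass: class probabilities for a batch
#'
#' @param model A [build_model()] network.
#' @param batch Numeric array `(B, 256, 2)` (a trailing singleton map axis,
#'   `(B, 256, 2, 1)`, is also accepted).
#' @param training Use batch statistics and dropout (`TRUE`) or running
#'   statistics in deterministic inference mode (`FALSE`, default).
#' @return Probability matrix `(B, 3)` with columns `W`, `N`, `R`; rows sum
#'   to 1.
#' @export
nn_forward <- function(model, batch, training = FALSE) {
  stopifnot(inherits(model, "resnet_model"))
  d <- dim(batch)
  if (length(d) == 4L && d[4L] == 1L) {
    batch <- array(batch, dim = d[1:3])
  } else if (length(d) == 2L) {        # single epoch (256, 2)
    batch <- array(batch, dim = c(1L, d))
  }
  if (!all(dim(batch)[2:3] == c(256L, 2L))) {
    stop("batch must be shaped (B, 256, 2)")
  }
  probs <- .model_forward(model, batch, training = training)
  colnames(probs) <- c("W", "N", "R")
  probs
}

#' Count trainable parameters
#'
#' Convolution weights and biases, batch-norm scale/shift, and dense
#' weights/bias. Batch-norm running statistics are not trainable and are
#' excluded.
#'
#' @param model A [build_model()] network.
#' @return Integer parameter count.
#' @export
count_trainable_parameters <- function(model) {
  sum(vapply(.model_layers(model),
             function(ly) sum(vapply(ly$P, length, 1L)), 1L))
}

#' Per-layer architecture summary
#'
#' One row per layer: block, layer name, output shape and parameter counts
#' (trainable and, for batch norm, the non-trainable running statistics).
#'
#' @param model A [build_model()] network.
#' @return A data.frame.
#' @export
model_summary <- function(model) {
  rows <- list()
  add <- function(block, name, maps, trainable, non_trainable = 0L) {
    rows[[length(rows) + 1L]] <<- data.frame(
      block = block, layer = name,
      output_shape = sprintf("(256, 2, %d)", maps),
      trainable_params = trainable, non_trainable_params = non_trainable,
      stringsAsFactors = FALSE)
  }
  for (i in seq_along(model$blocks)) {
    bl <- model$blocks[[i]]
    conv_p <- function(cv) sum(vapply(cv$P, length, 1L))
    add(i, "conv2d_1 (2,1)", bl$out_maps, conv_p(bl$conv1))
    add(i, "batch_norm_1", bl$out_maps, 2L * bl$out_maps, 2L * bl$out_maps)
    add(i, "conv2d_2 (2,1)", bl$out_maps, conv_p(bl$conv2))
    add(i, "batch_norm_2", bl$out_maps, 2L * bl$out_maps, 2L * bl$out_maps)
    add(i, "conv2d_3 (2,1)", bl$out_maps, conv_p(bl$conv3))
    add(i, "batch_norm_3", bl$out_maps, 2L * bl$out_maps, 2L * bl$out_maps)
    if (!is.null(bl$proj_conv)) {
      add(i, "shortcut_conv (1,1)", bl$out_maps, conv_p(bl$proj_conv))
      add(i, "shortcut_batch_norm", bl$out_maps, 2L * bl$out_maps,
          2L * bl$out_maps)
    }
  }
  nf <- model$widths[length(model$widths)]
  rows[[length(rows) + 1L]] <- data.frame(
    block = NA_integer_, layer = "global_average_pooling",
    output_shape = sprintf("(%d)", nf),
    trainable_params = 0L, non_trainable_params = 0L,
    stringsAsFactors = FALSE)
  rows[[length(rows) + 1L]] <- data.frame(
    block = NA_integer_, layer = "dense_softmax",
    output_shape = sprintf("(%d)", model$cfg$n_classes),
    trainable_params = length(model$dense$P$W) + length(model$dense$P$b),
    non_trainable_params = 0L, stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

#' Save / load a trained model
#'
#' Serializes the configuration, all parameters and batch-norm running
#' statistics; `load_model()` rebuilds the network and restores them, so
#' forward outputs round-trip exactly.
#'
#' @param model A [build_model()] network.
#' @param path File path (`.rds`).
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the restored `resnet_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "resnet_model"))
  saveRDS(list(cfg = model$cfg, state = .model_state(model)), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  model <- build_model(obj$cfg)
  .model_restore(model, obj$state)
  model
}
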