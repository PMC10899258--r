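# Network engine -------------------------------------------------------------
#
# Activations for a batch of B epochs are carried as a (maps x L) matrix with
# L = 512 * B columns ordered time-fastest: column j holds the feature vector
# at (t, c, b) with j = t + 256*(c-1) + 512*(b-1). A (2,1) convolution along
# the time axis with "same" padding is then two matrix products,
#   Y = W1 X + W2 shift(X) + b,
# where shift() advances each (channel, sample) stripe by one time step and
# zero-pads the stripe end (right-padding, as in the usual "same" convention
# for even kernels). The transposed kernel orientation (1,2) shifts across
# the channel axis instead. All layers are mutable environments carrying
# parameters, gradients and Adam state.

.TIME_LEN <- 256L
.N_CHANNELS <- 2L
.COLS_PER_SAMPLE <- 512L

.shift_fwd <- function(x, axis) {
  L <- ncol(x)
  if (axis == "time") {
    xs <- x[, c(seq_len(L)[-1L], 1L), drop = FALSE]
    xs[, seq.int(.TIME_LEN, L, by = .TIME_LEN)] <- 0
  } else {
    xs <- matrix(0, nrow(x), L)
    src <- which((((seq_len(L) - 1L) %/% .TIME_LEN) %% .N_CHANNELS) == 0L)
    xs[, src] <- x[, src + .TIME_LEN]
  }
  xs
}

# adjoint of .shift_fwd: scatter gradient back to the unshifted positions
.shift_bwd <- function(g, axis) {
  L <- ncol(g)
  if (axis == "time") {
    u <- g[, c(L, seq_len(L - 1L)), drop = FALSE]
    u[, seq.int(1L, L, by = .TIME_LEN)] <- 0
  } else {
    u <- matrix(0, nrow(g), L)
    src <- which((((seq_len(L) - 1L) %/% .TIME_LEN) %% .N_CHANNELS) == 0L)
    u[, src + .TIME_LEN] <- g[, src]
  }
  u
}

.new_conv <- function(in_maps, out_maps, taps = 2L, axis = "time") {
  ly <- new.env(parent = emptyenv())
  ly$type <- "conv"
  ly$in_maps <- in_maps
  ly$out_maps <- out_maps
  ly$taps <- taps
  ly$axis <- axis
  sd <- sqrt(2 / (taps * in_maps))     # He initialization for ReLU stacks
  ly$P <- c(
    stats::setNames(
      lapply(seq_len(taps), function(k)
        matrix(stats::rnorm(out_maps * in_maps, sd = sd), out_maps, in_maps)),
      paste0("W", seq_len(taps))),
    list(b = numeric(out_maps))
  )
  ly
}

.conv_forward <- function(ly, x) {
  ly$x <- x
  y <- ly$P$W1 %*% x
  if (ly$taps == 2L) {
    ly$xs <- .shift_fwd(x, ly$axis)
    y <- y + ly$P$W2 %*% ly$xs
  }
  y + ly$P$b
}

.conv_backward <- function(ly, dy) {
  ly$G <- list(W1 = dy %*% t(ly$x))
  dx <- crossprod(ly$P$W1, dy)
  if (ly$taps == 2L) {
    ly$G$W2 <- dy %*% t(ly$xs)
    dx <- dx + .shift_bwd(crossprod(ly$P$W2, dy), ly$axis)
  }
  ly$G$b <- rowSums(dy)
  ly$x <- NULL; ly$xs <- NULL
  dx
}

.new_batchnorm <- function(maps, momentum = 0.9, eps = 1e-3) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "batchnorm"
  ly$maps <- maps
  ly$momentum <- momentum
  ly$eps <- eps
  ly$P <- list(gamma = rep(1, maps), beta = numeric(maps))
  ly$running_mean <- numeric(maps)
  ly$running_var <- rep(1, maps)
  ly
}

.bn_forward <- function(ly, x, training) {
  if (training) {
    mu <- rowMeans(x)
    xc <- x - mu
    v <- rowMeans(xc * xc)
    istd <- 1 / sqrt(v + ly$eps)
    ly$xhat <- xc * istd
    ly$istd <- istd
    ly$running_mean <- ly$momentum * ly$running_mean + (1 - ly$momentum) * mu
    ly$running_var <- ly$momentum * ly$running_var + (1 - ly$momentum) * v
    ly$P$gamma * ly$xhat + ly$P$beta
  } else {
    istd <- 1 / sqrt(ly$running_var + ly$eps)
    (x - ly$running_mean) * istd * ly$P$gamma + ly$P$beta
  }
}

.bn_backward <- function(ly, dy) {
  xhat <- ly$xhat
  ly$G <- list(gamma = rowSums(dy * xhat), beta = rowSums(dy))
  dxhat <- dy * ly$P$gamma
  # d/dx of per-map normalization over all L columns
  dx <- ly$istd * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  ly$xhat <- NULL; ly$istd <- NULL
  dx
}

.new_dropout <- function(rate) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "dropout"
  ly$rate <- rate
  ly$P <- list()
  ly
}

.dropout_forward <- function(ly, x, training) {
  if (!training || ly$rate <= 0) return(x)
  keep <- 1 - ly$rate
  ly$mask <- (matrix(stats::runif(length(x)), nrow(x)) < keep) / keep
  x * ly$mask
}

.dropout_backward <- function(ly, dy) {
  if (ly$rate <= 0) return(dy)
  dy * ly$mask
}

.new_dense <- function(in_features, out_features) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "dense"
  # zero init: a fresh model emits exactly uniform class probabilities
  ly$P <- list(W = matrix(0, out_features, in_features),
               b = numeric(out_features))
  ly
}

.dense_forward <- function(ly, f) {
  ly$f <- f
  ly$P$W %*% f + ly$P$b
}

.dense_backward <- function(ly, dy) {
  ly$G <- list(W = dy %*% t(ly$f), b = rowSums(dy))
  ly$f <- NULL
  crossprod(ly$P$W, dy)
}

# residual block: [conv-BN-dropout-ReLU] x2 + conv-BN, identity or projected
# shortcut, elementwise add, final ReLU
.new_block <- function(in_maps, out_maps, dropout_rate = 0, axis = "time") {
  bl <- new.env(parent = emptyenv())
  bl$in_maps <- in_maps
  bl$out_maps <- out_maps
  bl$conv1 <- .new_conv(in_maps, out_maps, taps = 2L, axis = axis)
  bl$bn1 <- .new_batchnorm(out_maps)
  bl$do1 <- .new_dropout(dropout_rate)
  bl$conv2 <- .new_conv(out_maps, out_maps, taps = 2L, axis = axis)
  bl$bn2 <- .new_batchnorm(out_maps)
  bl$do2 <- .new_dropout(dropout_rate)
  bl$conv3 <- .new_conv(out_maps, out_maps, taps = 2L, axis = axis)
  bl$bn3 <- .new_batchnorm(out_maps)
  if (in_maps != out_maps) {          # 1x1 projection shortcut
    bl$proj_conv <- .new_conv(in_maps, out_maps, taps = 1L, axis = axis)
    bl$proj_bn <- .new_batchnorm(out_maps)
  } else {
    bl$proj_conv <- NULL
    bl$proj_bn <- NULL
  }
  bl
}

.block_forward <- function(bl, x, training) {
  a1 <- .dropout_forward(bl$do1,
          .bn_forward(bl$bn1, .conv_forward(bl$conv1, x), training), training)
  bl$m1 <- a1 > 0
  h1 <- a1 * bl$m1
  a2 <- .dropout_forward(bl$do2,
          .bn_forward(bl$bn2, .conv_forward(bl$conv2, h1), training), training)
  bl$m2 <- a2 > 0
  h2 <- a2 * bl$m2
  body <- .bn_forward(bl$bn3, .conv_forward(bl$conv3, h2), training)
  sc <- if (is.null(bl$proj_conv)) x else {
    .bn_forward(bl$proj_bn, .conv_forward(bl$proj_conv, x), training)
  }
  z <- body + sc
  bl$mz <- z > 0
  z * bl$mz
}

.block_backward <- function(bl, dy) {
  dz <- dy * bl$mz
  dbody <- .conv_backward(bl$conv3, .bn_backward(bl$bn3, dz))
  dh2 <- dbody * bl$m2
  dh2 <- .dropout_backward(bl$do2, dh2)
  dh1 <- .conv_backward(bl$conv2, .bn_backward(bl$bn2, dh2)) * bl$m1
  dh1 <- .dropout_backward(bl$do1, dh1)
  dx <- .conv_backward(bl$conv1, .bn_backward(bl$bn1, dh1))
  dsc <- if (is.null(bl$proj_conv)) dz else {
    .conv_backward(bl$proj_conv, .bn_backward(bl$proj_bn, dz))
  }
  bl$m1 <- NULL; bl$m2 <- NULL; bl$mz <- NULL
  dx + dsc
}

.block_layers <- function(bl) {
  ls <- list(bl$conv1, bl$bn1, bl$do1, bl$conv2, bl$bn2, bl$do2,
             bl$conv3, bl$bn3)
  if (!is.null(bl$proj_conv)) ls <- c(ls, list(bl$proj_conv, bl$proj_bn))
  ls
}

# batch array (B, 256, 2) -> engine layout (1 x 512B)
.batch_to_matrix <- function(batch) {
  stopifnot(length(dim(batch)) == 3L,
            dim(batch)[2L] == .TIME_LEN, dim(batch)[3L] == .N_CHANNELS)
  matrix(as.numeric(aperm(batch, c(2L, 3L, 1L))), nrow = 1L)
}

.gap_forward <- function(h, B) {
  # mean over the 512 (time x channel) columns of each sample
  f <- t(rowsum(t(h), group = rep(seq_len(B), each = .COLS_PER_SAMPLE))) /
    .COLS_PER_SAMPLE
  dimnames(f) <- NULL
  f
}

.gap_backward <- function(df, B) {
  df[, rep(seq_len(B), each = .COLS_PER_SAMPLE), drop = FALSE] /
    .COLS_PER_SAMPLE
}

.softmax_cols <- function(logits) {
  z <- exp(sweep(logits, 2L, apply(logits, 2L, max)))
  sweep(z, 2L, colSums(z), "/")
}

# forward pass through the whole network.
# batch: (B, 256, 2) array; returns (B, 3) probability matrix
.model_forward <- function(model, batch, training = FALSE) {
  B <- dim(batch)[1L]
  h <- .batch_to_matrix(batch)
  for (bl in model$blocks) h <- .block_forward(bl, h, training)
  f <- .gap_forward(h, B)
  logits <- .dense_forward(model$dense, f)
  probs <- .softmax_cols(logits)
  model$last_B <- B
  t(probs)
}

# backward pass given (B, 3) one-hot targets and (B, 3) probabilities;
# leaves gradients in each layer's $G. Returns the mean cross-entropy loss.
.model_backward <- function(model, probs, targets) {
  B <- nrow(probs)
  p <- t(probs)
  y <- t(targets)
  loss <- -sum(y * log(pmax(p, 1e-12))) / B
  dlogits <- (p - y) / B
  df <- .dense_backward(model$dense, dlogits)
  dh <- .gap_backward(df, B)
  for (bl in rev(model$blocks)) dh <- .block_backward(bl, dh)
  loss
}

# all parameterized layers of a model, in a stable order
.model_layers <- function(model) {
  c(do.call(c, lapply(model$blocks, .block_layers)), list(model$dense))
}

# Adam ------------------------------------------------------------------

.adam_init <- function(model) {
  for (ly in .model_layers(model)) {
    ly$M <- lapply(ly$P, function(p) p * 0)
    ly$V <- lapply(ly$P, function(p) p * 0)
  }
  model$adam_t <- 0L
  invisible(model)
}

.adam_step <- function(model, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  model$adam_t <- model$adam_t + 1L
  t <- model$adam_t
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (ly in .model_layers(model)) {
    if (length(ly$P) == 0L) next
    for (nm in names(ly$P)) {
      g <- ly$G[[nm]]
      ly$M[[nm]] <- beta1 * ly$M[[nm]] + (1 - beta1) * g
      ly$V[[nm]] <- beta2 * ly$V[[nm]] + (1 - beta2) * g * g
      mhat <- ly$M[[nm]] / bc1
      vhat <- ly$V[[nm]] / bc2
      ly$P[[nm]] <- ly$P[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  invisible(model)
}

# snapshot / restore ----------------------------------------------------

.layer_state <- function(ly) {
  st <- list(P = ly$P)
  if (ly$type == "batchnorm") {
    st$running_mean <- ly$running_mean
    st$running_var <- ly$running_var
  }
  st
}

.layer_restore <- function(ly, st) {
  ly$P <- st$P
  if (ly$type == "batchnorm") {
    ly$running_mean <- st$running_mean
    ly$running_var <- st$running_var
  }
  invisible(ly)
}

.model_state <- function(model) {
  lapply(.model_layers(model), .layer_state)
}

.model_restore <- function(model, state) {
  lys <- .model_layers(model)
  stopifnot(length(lys) == length(state))
  for (i in seq_along(lys)) .layer_restore(lys[[i]], state[[i]])
  invisible(model)
}
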