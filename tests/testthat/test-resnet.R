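test_that("residual blocks follow the body/shortcut/merge contract", {
  # matching widths: identity shortcut, no projection parameters
  bl <- build_block(8, 8)
  expect_null(bl$proj_conv)
  # widening: 1x1 projection conv + batch norm appear
  bl2 <- build_block(8, 16)
  expect_false(is.null(bl2$proj_conv))
  expect_equal(dim(bl2$proj_conv$P$W1), c(16L, 8L))
  expect_error(build_block(0, 8), "positive")

  # residual-identity: zeroing the final conv makes the block ReLU(shortcut)
  bl3 <- build_block(4, 4)
  bl3$conv3$P$W1[] <- 0
  bl3$conv3$P$W2[] <- 0
  bl3$conv3$P$b[] <- 0
  x <- matrix(rnorm(4 * 1024), 4)     # one two-channel sample, 4 maps
  y <- sleepstager:::.block_forward(bl3, x, training = TRUE)
  expect_equal(y, pmax(x, 0))
})

test_that("the default network stacks 7 doubling blocks onto a 3-way softmax", {
  cfg <- model_config()
  expect_equal(cfg$learning_rate, 1e-6)
  expect_equal(cfg$batch_size, 128L)
  m <- build_model(cfg)
  expect_length(m$blocks, 7L)
  expect_equal(m$widths, c(8L, 16L, 32L, 64L, 128L, 256L, 512L))
  expect_equal(dim(m$dense$P$W), c(3L, 512L))

  set.seed(8)
  batch <- array(rnorm(2 * 256 * 2), c(2, 256, 2))
  p <- nn_forward(m, batch)
  expect_equal(dim(p), c(2L, 3L))
  expect_equal(rowSums(p), c(1, 1), tolerance = 1e-5)
  expect_true(all(p >= 0 & p <= 1))

  # test-scale model obeys the doubling rule
  m2 <- build_model(model_config(n_resnet_blocks = 2L, n_feature_maps = 4L))
  expect_equal(m2$widths, c(4L, 8L))

  # the transposed kernel orientation builds and runs
  m3 <- build_model(model_config(n_resnet_blocks = 2L, n_feature_maps = 4L,
                                 kernel_axis = "channel"))
  p3 <- nn_forward(m3, batch)
  expect_equal(rowSums(p3), c(1, 1), tolerance = 1e-5)
})

test_that("forward passes are deterministic and batch-equivariant", {
  m <- build_model(model_config(n_resnet_blocks = 2L, n_feature_maps = 4L,
                                seed = 3L))
  set.seed(31)
  batch <- array(rnorm(6 * 256 * 2), c(6, 256, 2))

  # single-sample input accepted, probabilities normalized
  p1 <- nn_forward(m, batch[1, , ])
  expect_equal(sum(p1), 1, tolerance = 1e-5)

  # duplicated rows give identical outputs
  dup <- batch[c(1, 1, 2), , , drop = FALSE]
  pd <- nn_forward(m, dup)
  expect_equal(pd[1, ], pd[2, ])

  # permuting the batch permutes the outputs
  perm <- c(4, 2, 6, 1, 3, 5)
  expect_equal(nn_forward(m, batch)[perm, ], nn_forward(m, batch[perm, , ]))

  # trailing singleton map axis accepted
  p4 <- nn_forward(m, array(batch, c(6, 256, 2, 1)))
  expect_equal(p4, nn_forward(m, batch))

  expect_error(nn_forward(m, array(0, c(2, 100, 2))), "256")
})

test_that("a fresh model is unbiased across classes", {
  m <- build_model(model_config(n_resnet_blocks = 2L, n_feature_maps = 4L,
                                seed = 12L))
  set.seed(99)
  batch <- array(rnorm(1024 * 256 * 2), c(1024, 256, 2))
  avg <- colMeans(predict_stages(m, batch))
  expect_true(all(abs(avg - 1 / 3) < 0.15))
})

test_that("parameter counts match closed forms and a layer-by-layer oracle", {
  # 8 filters, kernel (2,1), one input map: 8*(2*1*1) + 8 = 24
  cv <- sleepstager:::.new_conv(1L, 8L, taps = 2L)
  expect_equal(sum(vapply(cv$P, length, 1L)), 24L)
  # batch norm over 8 maps: 16 trainable (gamma, beta)
  bn <- sleepstager:::.new_batchnorm(8L)
  expect_equal(sum(vapply(bn$P, length, 1L)), 16L)

  # independent summation over the published block contract
  hand_count <- function(n_blocks, n_maps, n_classes = 3L) {
    total <- 0L
    in_maps <- 1L
    for (i in seq_len(n_blocks)) {
      out <- n_maps * 2L^(i - 1L)
      conv <- function(kt, ni, no) no * kt * ni + no
      total <- total + conv(2L, in_maps, out) + 2L * conv(2L, out, out) +
        3L * 2L * out +                          # three batch norms
        (if (in_maps != out) conv(1L, in_maps, out) + 2L * out else 0L)
      in_maps <- out
    }
    total + n_classes * in_maps + n_classes     # dense softmax
  }
  m <- build_model(model_config())
  expect_equal(count_trainable_parameters(m), hand_count(7L, 8L))
  m2 <- build_model(model_config(n_resnet_blocks = 2L, n_feature_maps = 4L))
  expect_equal(count_trainable_parameters(m2), hand_count(2L, 4L))

  # the architecture summary agrees with the total
  summ <- model_summary(m)
  expect_equal(sum(summ$trainable_params), count_trainable_parameters(m))
  expect_equal(summ$output_shape[1], "(256, 2, 8)")
})

test_that("models serialize and restore with identical forward outputs", {
  m <- build_model(model_config(n_resnet_blocks = 2L, n_feature_maps = 4L,
                                seed = 77L))
  set.seed(5)
  batch <- array(rnorm(4 * 256 * 2), c(4, 256, 2))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(nn_forward(m2, batch), nn_forward(m, batch))
  expect_equal(count_trainable_parameters(m2), count_trainable_parameters(m))
})
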