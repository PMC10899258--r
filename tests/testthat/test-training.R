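test_that("stratified folds are balanced, disjoint and covering", {
  labels <- stage_onehot(c(rep("W", 50), rep("N", 40), rep("R", 10)))
  folds <- stratified_kfold(labels, k = 5, seed = 1)
  stages <- onehot_to_stage(labels)
  for (f in folds) {
    tab <- table(factor(stages[f$test_idx], c("W", "N", "R")))
    expect_equal(unname(as.integer(tab)), c(10L, 8L, 2L))
    expect_length(f$test_idx, 20L)
    expect_length(intersect(f$train_idx, f$test_idx), 0L)
  }
  expect_setequal(unlist(lapply(folds, `[[`, "test_idx")), seq_len(100))
  expect_equal(sum(lengths(lapply(folds, `[[`, "test_idx"))), 100L)

  # determinism
  folds2 <- stratified_kfold(labels, k = 5, seed = 1)
  expect_identical(folds, folds2)
  folds3 <- stratified_kfold(labels, k = 5, seed = 2)
  expect_false(identical(folds, folds3))

  expect_error(stratified_kfold(stage_onehot(c("W", "W", "N", "N", "R")),
                                k = 5), "at least k")
})

test_that("stratification holds for arbitrary label mixes", {
  set.seed(20)
  for (rep in 1:20) {
    n <- sample(60:400, 1)
    stages <- sample(c("W", "N", "R"), n, replace = TRUE,
                     prob = stats::runif(3, 0.2, 1))
    if (min(table(stages)) < 5) next
    folds <- stratified_kfold(stages, k = 5, seed = rep)
    counts <- table(factor(stages, c("W", "N", "R")))
    for (f in folds) {
      test_tab <- table(factor(stages[f$test_idx], c("W", "N", "R")))
      # per-class proportions within one sample of the global split on
      # both sides of every fold
      expect_true(all(abs(test_tab - counts / 5) <= 1))
      train_tab <- table(factor(stages[f$train_idx], c("W", "N", "R")))
      expect_true(all(abs(train_tab - counts * 4 / 5) <= 1))
    }
  }
})

test_that("the plateau schedule halves the rate after 3 flat passes", {
  # a learning rate so small that no pass can improve the loss by more than
  # the improvement tolerance: pass 1 improves (from infinity), every later
  # full-batch pass is flat, so the rate halves after passes 4 and 7
  ds <- tiny_dataset(n = 60L, seed = 7L)
  n <- dim(ds$signals)[1]
  l0 <- 1e-15
  cfg <- model_config(n_resnet_blocks = 1L, n_feature_maps = 2L,
                      learning_rate = l0, num_epochs = 8L,
                      batch_size = 512L, seed = 5L, lr_floor = 1e-20)
  split <- list(fold_id = 1L, train_idx = seq_len(n - 10L),
                test_idx = (n - 9L):n)
  fit <- train_fold(ds, split, cfg)
  h <- fit$history
  expect_equal(h$lr, c(l0, l0, l0, l0, l0 / 2, l0 / 2, l0 / 2, l0 / 4))
  expect_true(all(diff(h$lr) <= 0))
  # checkpoint contract: best monitored loss equals the history minimum
  expect_equal(attr(h, "best_loss"), min(h$train_loss))
})

test_that("no held-out index ever enters a gradient update", {
  ds <- tiny_dataset(n = 80L, seed = 7L)
  folds <- stratified_kfold(ds$labels, k = 5, seed = 2)
  cfg <- model_config(n_resnet_blocks = 1L, n_feature_maps = 2L,
                      learning_rate = 1e-4, num_epochs = 2L,
                      batch_size = 16L, seed = 5L)
  fit <- train_fold(ds, folds[[2]], cfg)
  used <- attr(fit$history, "train_indices_used")
  # indices are relative to the training subset and must cover it exactly
  expect_setequal(used, seq_along(folds[[2]]$train_idx))
})

test_that("training is reproducible from the seeds", {
  ds <- tiny_dataset(n = 80L, seed = 7L)
  folds <- stratified_kfold(ds$labels, k = 5, seed = 2)
  cfg <- model_config(n_resnet_blocks = 1L, n_feature_maps = 2L,
                      learning_rate = 1e-4, num_epochs = 2L,
                      batch_size = 16L, seed = 9L)
  f1 <- train_fold(ds, folds[[1]], cfg, aug = augment_config())
  f2 <- train_fold(ds, folds[[1]], cfg, aug = augment_config())
  expect_equal(f1$history$train_loss, f2$history$train_loss)
  expect_equal(f1$history$val_acc, f2$history$val_acc)
  set.seed(101)
  batch <- array(rnorm(2 * 256 * 2), c(2, 256, 2))
  expect_identical(nn_forward(f1$model, batch), nn_forward(f2$model, batch))
})

test_that("cross-validation reports the per-fold table with mean and SEM", {
  ds <- tiny_dataset(n = 400L, seed = 17L)
  cfg <- model_config(n_resnet_blocks = 2L, n_feature_maps = 4L,
                      learning_rate = 1e-4, num_epochs = 3L,
                      batch_size = 8L, seed = 3L)
  cv <- suppressWarnings(cross_validate(ds, cfg, k = 5, seed = 3))
  m <- cv$metrics
  expect_equal(nrow(m), 7L)                        # 5 folds + mean + sem
  expect_equal(m$fold, c("1", "2", "3", "4", "5", "mean", "sem"))
  metric_cols <- setdiff(names(m), "fold")
  expect_length(metric_cols, 15L)                  # 5 metrics x 3 stages
  fold_rows <- m[1:5, metric_cols]
  expect_equal(unname(unlist(m[6, metric_cols])),
               unname(colMeans(fold_rows)))
  expect_equal(unname(unlist(m[7, metric_cols])),
               unname(apply(fold_rows, 2, stats::sd) / sqrt(5)))
  expect_length(cv$confusions, 5L)
  expect_equal(sum(cv$confusions[[1]]), length(cv$folds[[1]]$test_idx))
})

test_that("the final model trains on everything and serializes with provenance", {
  ds <- tiny_dataset(n = 100L, seed = 7L)
  cfg <- model_config(n_resnet_blocks = 1L, n_feature_maps = 2L,
                      learning_rate = 1e-4, num_epochs = 2L,
                      batch_size = 16L, seed = 4L)
  out <- train_final(ds, cfg)
  expect_equal(nrow(out$history), 2L)
  expect_equal(out$manifest[["seed"]], "4")
  expect_equal(out$manifest[["optimizer_name"]], "Adam")
  expect_true(nzchar(out$manifest[["data_fingerprint"]]))

  path <- withr::local_tempfile(fileext = ".rds")
  save_model(out$model, path)
  reloaded <- load_model(path)
  probs <- predict_stages(out$model, ds)
  expect_identical(predict_stages(reloaded, ds), probs)
})
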