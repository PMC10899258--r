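test_that("confusion matrices count true/predicted pairs exactly", {
  cm <- confusion_matrix(c("W", "N", "R"), c("W", "N", "R"))
  expect_equal(unname(diag(cm)), c(1L, 1L, 1L))
  expect_equal(sum(cm) - sum(diag(cm)), 0L)

  cm2 <- confusion_matrix(rep("W", 7), rep("N", 7))
  expect_equal(cm2["W", "N"], 7L)
  expect_equal(sum(cm2), 7L)

  set.seed(10)
  true <- sample(c("W", "N", "R"), 200, replace = TRUE)
  pred <- sample(c("W", "N", "R"), 200, replace = TRUE)
  cm3 <- confusion_matrix(true, pred)
  for (i in c("W", "N", "R")) for (j in c("W", "N", "R")) {
    expect_equal(cm3[i, j], sum(true == i & pred == j))
  }
  expect_equal(unname(rowSums(cm3)),
               unname(as.integer(table(factor(true, c("W", "N", "R"))))))

  expect_error(confusion_matrix("W", c("W", "N")), "equal length")
  expect_error(confusion_matrix("W", "X"), "W/N/R")
})

test_that("per-class metrics agree with a brute-force oracle", {
  set.seed(11)
  for (rep in 1:1000) {
    cm <- matrix(sample.int(50, 9, replace = TRUE) - 1L, 3, 3,
                 dimnames = list(true = c("W", "N", "R"),
                                 pred = c("W", "N", "R")))
    if (sum(cm) == 0) next
    class(cm) <- c("confusion_matrix", class(cm))
    s <- sample(c("W", "N", "R"), 1)
    i <- match(s, c("W", "N", "R"))
    tp <- cm[i, i]; fp <- sum(cm[-i, i]); fn <- sum(cm[i, -i])
    tn <- sum(cm) - tp - fp - fn
    got <- suppressWarnings(per_class_metrics(cm, s))
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    expect_equal(unname(got), c((tp + tn) / sum(cm), p, r, f) * 100)
  }

  # harmonic-mean fixed point and zero guards
  cm <- confusion_matrix(c("W", "W", "N", "N"), c("W", "N", "W", "N"))
  pm <- per_class_metrics(cm, "W")       # precision = recall = 50
  expect_equal(pm[["f1"]], pm[["precision"]])
  cm0 <- confusion_matrix(rep("N", 5), rep("W", 5))
  ws <- capture_warnings(pm0 <- per_class_metrics(cm0, "R"))
  expect_true(all(grepl("zero|reported as 0", ws)))
  expect_equal(unname(pm0[c("precision", "recall", "f1")]), c(0, 0, 0))
})

test_that("Cohen's kappa matches its definition and limiting behavior", {
  # perfect agreement with mixed marginals
  cm <- confusion_matrix(c(rep("W", 5), rep("N", 3), rep("R", 2)),
                         c(rep("W", 5), rep("N", 3), rep("R", 2)))
  expect_equal(cohens_kappa(cm), 1)

  # hand-computed 2x2 case: po = 0.7, pe = 0.5 -> kappa = 0.4
  m22 <- matrix(c(40, 20, 10, 30), 2, 2)
  expect_equal(cohens_kappa(m22), (0.7 - 0.5) / (1 - 0.5))

  # independence gives kappa near zero
  set.seed(12)
  true <- sample(c("W", "N", "R"), 1e4, replace = TRUE, prob = c(.5, .4, .1))
  pred <- sample(c("W", "N", "R"), 1e4, replace = TRUE, prob = c(.5, .4, .1))
  expect_lt(abs(cohens_kappa(confusion_matrix(true, pred))), 0.05)

  # kappa = 1 iff no off-diagonal mass (non-degenerate marginals)
  cm2 <- confusion_matrix(c("W", "N", "R", "W"), c("W", "N", "R", "N"))
  expect_lt(cohens_kappa(cm2), 1)

  # one-vs-rest collapse equals kappa of the collapsed table
  set.seed(13)
  t3 <- sample(c("W", "N", "R"), 300, replace = TRUE)
  p3 <- sample(c("W", "N", "R"), 300, replace = TRUE)
  cm3 <- confusion_matrix(t3, p3)
  collapsed <- confusion_matrix(ifelse(t3 == "R", "W", "N"),
                                ifelse(p3 == "R", "W", "N"))
  expect_equal(cohens_kappa(cm3, stage = "R"), cohens_kappa(collapsed[1:2, 1:2]))
})

test_that("cross-entropy and explained variance match closed forms", {
  y <- stage_onehot(c("W", "N", "R"))
  expect_lt(categorical_cross_entropy(y, y), 1e-10)
  u <- matrix(1 / 3, 3, 3)
  expect_equal(categorical_cross_entropy(y, u), log(3))

  set.seed(14)
  probs <- matrix(stats::runif(30), 10, 3)
  probs <- probs / rowSums(probs)
  yy <- stage_onehot(sample(c("W", "N", "R"), 10, replace = TRUE))
  hand <- -mean(vapply(1:10, function(i) sum(yy[i, ] * log(probs[i, ])), 1))
  expect_equal(categorical_cross_entropy(yy, probs), hand)
  expect_error(categorical_cross_entropy(yy, probs[1:5, ]), "mismatch")

  v <- rnorm(50)
  expect_equal(explained_variance(v, v), 1)
  expect_equal(explained_variance(v, rep(mean(v), 50)), 0)
  expect_equal(explained_variance(v, v + 3.2), 1)
  expect_error(explained_variance(rep(1, 5), rnorm(5)), "undefined")
})

test_that("weighted overall metrics behave as convex combinations", {
  # uniform case: overall equals the common value
  ow <- overall_weighted_metrics(c(80, 80, 80), c(80, 80, 80))
  expect_equal(unname(ow), c(80, 80, 80))

  set.seed(15)
  for (rep in 1:50) {
    p <- stats::runif(3, 10, 100)
    r <- stats::runif(3, 10, 100)
    ow <- overall_weighted_metrics(p, r)
    expect_gte(ow[["overall_precision"]], min(p) - 1e-9)
    expect_lte(ow[["overall_precision"]], max(p) + 1e-9)
    # swapping precision and recall swaps the overalls, F1 unchanged
    sw <- overall_weighted_metrics(r, p)
    expect_equal(sw[["overall_precision"]], ow[["overall_recall"]])
    expect_equal(sw[["overall_f1"]], ow[["overall_f1"]])
  }
  expect_error(overall_weighted_metrics(c(0, 0, 0), c(0, 0, 0)), "undefined")
})

test_that("fold summaries compute mean and SEM with the n-1 denominator", {
  df <- data.frame(a = c(97.11, 96.66, 97.37, 96.72, 97.46),
                   b = c(1, 1, 1, 1, 1))
  fs <- fold_summary(df)
  expect_equal(fs["mean", "a"], mean(df$a))
  expect_equal(fs["sem", "a"], stats::sd(df$a) / sqrt(5))
  expect_equal(fs["sem", "b"], 0)

  two <- data.frame(x = c(3, 8))
  expect_equal(fold_summary(two)["sem", "x"], abs(3 - 8) / 2)
  expect_error(fold_summary(df[1, , drop = FALSE]), "at least 2")
})

test_that("the comparison report reproduces published overall metrics", {
  rep <- comparison_report()
  # the four prior models with full per-stage data are reproduced at the
  # printed 1-decimal precision
  for (mdl in c("MC-SleepNet", "Random Forest", "MASC", "LSTM",
                "MC-SleepNet (large)")) {
    i <- match(mdl, rep$model)
    j <- match(mdl, comparison_benchmark$model)
    expect_equal(round(rep$overall_precision[i], 1),
                 comparison_benchmark$overall_precision[j])
    expect_equal(round(rep$overall_recall[i], 1),
                 comparison_benchmark$overall_recall[j])
    expect_equal(round(rep$overall_f1[i], 1), comparison_benchmark$f1[j])
  }
  # FASTER has no published precisions
  expect_true(is.na(rep$overall_f1[match("FASTER", rep$model)]))
})
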