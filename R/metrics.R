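#' Confusion matrix over vigilance states
#'
#' Rows are true stages, columns predicted stages, both ordered (W, N, R).
#'
#' @param true,pred Character vectors of equal length with codes in
#'   `{W, N, R}`.
#' @return A 3x3 integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(true, pred) {
  if (length(true) != length(pred)) {
    stop("true and pred must have equal length (",
         length(true), " vs ", length(pred), ")")
  }
  lv <- c("W", "N", "R")
  bad <- setdiff(unique(c(true, pred)), lv)
  if (length(bad) > 0L) stop("stage codes must be W/N/R; got: ",
                             paste(bad, collapse = ", "))
  cm <- table(factor(true, levels = lv), factor(pred, levels = lv))
  cm <- matrix(as.integer(cm), 3L, 3L, dimnames = list(true = lv, pred = lv))
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

# one-vs-rest 2x2 collapse: rows/cols (stage, rest)
.ovr_counts <- function(cm, stage) {
  i <- match(stage, rownames(cm))
  tp <- cm[i, i]
  fp <- sum(cm[-i, i])
  fn <- sum(cm[i, -i])
  tn <- sum(cm[-i, -i])
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Per-stage one-vs-rest metrics
#'
#' Accuracy, precision, recall and F1 (all in percent) for one stage against
#' the rest: precision = TP/(TP+FP), recall = TP/(TP+FN), accuracy =
#' (TP+TN)/total, F1 = harmonic mean of precision and recall. Zero
#' denominators yield 0 with a warning so batch evaluation stays total.
#'
#' @param cm A [confusion_matrix()].
#' @param stage One of `"W"`, `"N"`, `"R"`.
#' @return Named numeric vector `(accuracy, precision, recall, f1)` in
#'   percent.
#' @export
per_class_metrics <- function(cm, stage) {
  k <- .ovr_counts(cm, stage)
  guard <- function(num, den, what) {
    if (den == 0) {
      warning("zero denominator for ", what, " (", stage, "); reporting 0")
      return(0)
    }
    num / den
  }
  precision <- guard(k["tp"], k["tp"] + k["fp"], "precision")
  recall <- guard(k["tp"], k["tp"] + k["fn"], "recall")
  accuracy <- (k["tp"] + k["tn"]) / sum(k)
  f1 <- if (precision + recall == 0) {
    warning("zero precision and recall (", stage, "); F1 reported as 0")
    0
  } else f1_score(precision, recall)
  c(accuracy = unname(accuracy) * 100, precision = unname(precision) * 100,
    recall = unname(recall) * 100, f1 = unname(f1) * 100)
}

#' F1 score from precision and recall
#'
#' The harmonic mean `2 P R / (P + R)`, on whatever scale (fraction or
#' percent) the inputs share; 0 when both inputs are 0.
#'
#' @param precision,recall Nonnegative scalars or equal-length vectors.
#' @return F1 on the same scale.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` where `p_o` is the
#' observed agreement (diagonal mass) and `p_e` the chance agreement implied
#' by the marginals. Accepts a full 3x3 matrix (overall kappa) or a 2x2
#' one-vs-rest collapse (per-stage kappa, see `stage`). Degenerate marginals
#' with `p_e = 1` yield 0.
#'
#' @param cm A square count matrix.
#' @param stage Optional stage code; when given, `cm` is first collapsed
#'   one-vs-rest for that stage.
#' @return Kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(cm, stage = NULL) {
  if (!is.null(stage)) {
    k <- .ovr_counts(cm, stage)
    cm <- matrix(c(k["tp"], k["fn"], k["fp"], k["tn"]), 2L, 2L)
  }
  cm <- matrix(as.numeric(cm), nrow(cm), ncol(cm))
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix")
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - pe) < 1e-15) return(0)
  (po - pe) / (1 - pe)
}

#' Mean categorical cross-entropy
#'
#' `-mean_i sum_c y_ic * ln(p_ic)` with probabilities clipped to
#' `[eps, 1]` for numerical safety.
#'
#' @param true_onehot Matrix `(N, 3)` of one-hot rows.
#' @param probs Matrix `(N, 3)` of predicted probabilities.
#' @param eps Clipping floor (default 1e-12).
#' @return Nonnegative scalar loss.
#' @export
categorical_cross_entropy <- function(true_onehot, probs, eps = 1e-12) {
  true_onehot <- as.matrix(true_onehot)
  probs <- as.matrix(probs)
  if (!all(dim(true_onehot) == dim(probs))) {
    stop("shape mismatch between labels and probabilities")
  }
  -mean(rowSums(true_onehot * log(pmin(pmax(probs, eps), 1))))
}

#' Explained variance
#'
#' `1 - Var(y - yhat) / Var(y)`; requires non-degenerate true values.
#'
#' @param true_values,predicted_values Equal-length numeric vectors, n >= 2.
#' @return Scalar fraction (1 for perfect prediction up to a constant
#'   offset, 0 for a constant prediction at the mean).
#' @export
explained_variance <- function(true_values, predicted_values) {
  if (length(true_values) != length(predicted_values)) {
    stop("length mismatch")
  }
  if (length(true_values) < 2L) stop("need at least 2 values")
  vy <- stats::var(true_values)
  if (vy == 0) stop("variance of the true values is zero; explained variance undefined")
  1 - stats::var(true_values - predicted_values) / vy
}

#' Recall/precision-weighted overall metrics
#'
#' Overall precision is the recall-weighted average of the per-stage
#' precisions; overall recall is the precision-weighted average of the
#' per-stage recalls; overall F1 is the harmonic mean of the two. This
#' weighting lets the more frequently identified stages dominate, giving a
#' single-figure summary comparable across classifiers with different stage
#' distributions.
#'
#' @param precision,recall Numeric 3-vectors in percent, ordered (W, N, R).
#' @return Named numeric vector `(overall_precision, overall_recall,
#'   overall_f1)` in percent.
#' @export
overall_weighted_metrics <- function(precision, recall) {
  stopifnot(length(precision) == 3L, length(recall) == 3L)
  if (sum(recall) == 0 || sum(precision) == 0) {
    stop("all-zero weights; overall metrics undefined")
  }
  op <- sum(precision * recall) / sum(recall)
  or <- sum(recall * precision) / sum(precision)
  c(overall_precision = op, overall_recall = or,
    overall_f1 = 2 * op * or / (op + or))
}

#' Column-wise mean and SEM of per-fold metric rows
#'
#' @param fold_rows A data.frame of numeric metric columns, one row per fold.
#' @return A data.frame with two rows, `mean` and `sem`
#'   (sample SD / sqrt(n)).
#' @export
fold_summary <- function(fold_rows) {
  fold_rows <- as.data.frame(fold_rows)
  num <- vapply(fold_rows, is.numeric, TRUE)
  if (nrow(fold_rows) < 2L) stop("need at least 2 fold rows")
  m <- vapply(fold_rows[num], mean, 1)
  s <- vapply(fold_rows[num], function(x) {
    stats::sd(x) / sqrt(length(x))
  }, 1)
  out <- rbind(as.data.frame(as.list(m)), as.data.frame(as.list(s)))
  rownames(out) <- c("mean", "sem")
  out
}

#' Full per-stage metric row from a confusion matrix
#'
#' The 15-column layout used by the cross-validation report: accuracy,
#' precision, recall, F1 (percent) and one-vs-rest kappa for each of W, N, R.
#'
#' @param cm A [confusion_matrix()].
#' @return A one-row data.frame with columns `<stage>_<metric>`.
#' @export
stage_metrics_row <- function(cm) {
  out <- list()
  for (s in c("W", "N", "R")) {
    pm <- per_class_metrics(cm, s)
    nm <- tolower(s)
    nm <- c(W = "wake", N = "nrem", R = "rem")[[s]]
    out[[paste0(nm, "_accuracy")]] <- pm[["accuracy"]]
    out[[paste0(nm, "_precision")]] <- pm[["precision"]]
    out[[paste0(nm, "_recall")]] <- pm[["recall"]]
    out[[paste0(nm, "_f1")]] <- pm[["f1"]]
    out[[paste0(nm, "_kappa")]] <- cohens_kappa(cm, stage = s)
  }
  as.data.frame(out)
}
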