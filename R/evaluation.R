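# Macro-averaged multi-class evaluation and paired significance testing.

#' Macro-averaged classification metrics
#'
#' Predictions are the row-wise argmax of the probability matrix. Per-class
#' precision, recall and F1 use the 0/0 -> 0 convention (a class never
#' predicted scores 0 precision); macro values are unweighted means over all
#' `K` classes. AUC is one-vs-rest, computed per class from the Mann-Whitney
#' rank statistic (ties get average ranks) and averaged over the classes
#' actually present in the truth with at least one negative; truth-absent
#' classes are excluded from the AUC mean but still count 0 in the
#' precision/recall/F1 means.
#'
#' @param true_labels Integer labels in `1..K`.
#' @param probability_matrix `n x K` matrix; every row must sum to 1
#'   (tolerance 1e-4).
#' @return An object of class `metrics_report`: accuracy, macro_precision,
#'   macro_recall, macro_f1, macro_auc, per_class_f1 (length `K`), and the
#'   `K x K` confusion matrix (rows = true, columns = predicted).
#' @examples
#' p <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
#' compute_metrics(c(1, 2), p)$accuracy
#' @export
compute_metrics <- function(true_labels, probability_matrix) {
  p <- as.matrix(probability_matrix)
  k <- ncol(p)
  n <- nrow(p)
  if (length(true_labels) != n) stop("label/probability length mismatch")
  if (any(abs(rowSums(p) - 1) > 1e-4)) {
    stop("probability rows must sum to 1 (tolerance 1e-4)")
  }
  if (any(true_labels < 1L | true_labels > k)) stop("labels must lie in 1..", k)
  pred <- max.col(p, ties.method = "first")
  confusion <- matrix(0L, k, k)
  for (i in seq_len(n)) {
    confusion[true_labels[i], pred[i]] <- confusion[true_labels[i], pred[i]] + 1L
  }
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  prec <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  rec <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  aucs <- vapply(seq_len(k), function(cls) {
    pos <- true_labels == cls
    n1 <- sum(pos); n0 <- n - n1
    if (n1 == 0L || n0 == 0L) return(NA_real_)
    r <- rank(p[, cls])
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, 1)
  structure(list(accuracy = sum(tp) / n,
                 macro_precision = mean(prec),
                 macro_recall = mean(rec),
                 macro_f1 = mean(f1),
                 macro_auc = if (all(is.na(aucs))) NA_real_ else mean(aucs, na.rm = TRUE),
                 per_class_f1 = f1,
                 confusion = confusion),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f | macro P %.4f R %.4f F1 %.4f AUC %.4f\n",
              x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1,
              x$macro_auc))
  invisible(x)
}

#' Paired bootstrap test on an accuracy difference
#'
#' Two-sided paired bootstrap over records: resamples record indices with
#' replacement, recomputes the accuracy difference of the two prediction
#' vectors on each resample, and reports `2 * min(Pr(diff* <= 0),
#' Pr(diff* >= 0))` with an add-one correction, capped at 1. Identical
#' predictions give p = 1; deterministic under the seed.
#'
#' @param pred_a,pred_b Equal-length predicted label vectors on the same
#'   records.
#' @param true_labels True labels of those records.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @return A single p-value in (0, 1].
#' @export
paired_significance <- function(pred_a, pred_b, true_labels, n_boot = 2000L,
                                seed = 1L) {
  n <- length(true_labels)
  if (length(pred_a) != n || length(pred_b) != n) {
    stop("prediction vectors must match the number of records")
  }
  ca <- as.integer(pred_a == true_labels)
  cb <- as.integer(pred_b == true_labels)
  if (all(pred_a == pred_b)) return(1)
  d <- withr::with_seed(seed, vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    mean(ca[idx]) - mean(cb[idx])
  }, 1))
  p_low <- (1 + sum(d <= 0)) / (n_boot + 1)
  p_high <- (1 + sum(d >= 0)) / (n_boot + 1)
  min(1, 2 * min(p_low, p_high))
}
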