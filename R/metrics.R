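# Evaluation toolkit: confusion matrix, accuracy, per-class/macro/weighted F1,
# and the exact (binomial) McNemar paired test for comparing two classifiers
# on the same samples.

#' Confusion matrix
#'
#' Tallies (true, predicted) label pairs into an `n x n` integer matrix with
#' rows indexing the true class and columns the predicted class. Labels are
#' 0-based, matching the manifest/class-ID convention used throughout the
#' package.
#'
#' @param truth,pred Equal-length integer vectors of 0-based labels in `[0, n)`.
#' @param n Number of classes.
#' @return Integer matrix with `dimnames` set to the 0-based class IDs.
#' @export
confusion <- function(truth, pred, n) {
  if (length(truth) != length(pred))
    stop("confusion: label vectors differ in length", call. = FALSE)
  if (length(truth) > 0 && (any(truth < 0 | truth >= n) || any(pred < 0 | pred >= n)))
    stop("confusion: label outside [0, n)", call. = FALSE)
  cm <- matrix(0L, n, n, dimnames = list(true = 0:(n - 1), pred = 0:(n - 1)))
  if (length(truth) > 0) {
    tab <- table(factor(truth, levels = 0:(n - 1)), factor(pred, levels = 0:(n - 1)))
    cm[] <- as.integer(tab)
  }
  cm
}

#' Overall accuracy from a confusion matrix
#'
#' The fraction of correctly classified samples, `trace(cm) / sum(cm)`.
#'
#' @param cm Confusion matrix from [confusion()].
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  total <- sum(cm)
  if (total < 1) stop("accuracy: empty confusion matrix", call. = FALSE)
  sum(diag(cm)) / total
}

#' Per-class, macro, and weighted F1 scores
#'
#' Per-class F1 is the harmonic mean of precision `TP/(TP+FP)` and recall
#' `TP/(TP+FN)`, with the 0/0 convention resolved to 0 (standard practice for
#' macro averaging under class imbalance). Macro F1 is the unweighted mean
#' over classes; weighted F1 weights each class by its true sample count, so
#' classes absent from the evaluation set carry zero weight.
#'
#' @param cm Confusion matrix from [confusion()].
#' @return List with `per_class` (vector), `macro`, `weighted`, `support`
#'   (true counts per class), and `empty_classes` (0-based IDs of classes
#'   with no true samples, flagged because they contribute F1 = 0 to macro).
#' @export
f1_scores <- function(cm) {
  n <- nrow(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  support <- rowSums(cm)
  weighted <- if (sum(support) > 0) sum(support * f1) / sum(support) else NaN
  list(per_class = as.numeric(f1),
       macro = mean(f1),
       weighted = weighted,
       support = as.numeric(support),
       empty_classes = which(support == 0) - 1L)
}

#' Full metrics report from label vectors
#'
#' Convenience wrapper computing the confusion matrix and all derived
#' metrics in one pass.
#'
#' @param truth,pred 0-based label vectors.
#' @param n Number of classes.
#' @return List with `accuracy`, `per_class_f1`, `macro_f1`, `weighted_f1`,
#'   `n_samples`, `n_correct`, and the `confusion` matrix.
#' @export
metrics_report <- function(truth, pred, n) {
  cm <- confusion(truth, pred, n)
  f <- f1_scores(cm)
  list(accuracy = accuracy(cm), per_class_f1 = f$per_class, macro_f1 = f$macro,
       weighted_f1 = f$weighted, n_samples = sum(cm), n_correct = sum(diag(cm)),
       empty_classes = f$empty_classes, confusion = cm)
}

#' Exact McNemar paired test
#'
#' Two-sided exact binomial test on the discordant pairs of two classifiers
#' evaluated on the same samples: with `b` = #(A correct, B wrong) and
#' `c` = #(A wrong, B correct), the p-value is
#' `min(1, 2 * P(X <= min(b, c)))` for `X ~ Binomial(b + c, 1/2)`.
#'
#' @param correct_a,correct_b Equal-length logical vectors of per-sample
#'   correctness for the two classifiers.
#' @return List with `p_value`, `b`, `c`.
#' @export
mcnemar_exact <- function(correct_a, correct_b) {
  if (length(correct_a) != length(correct_b))
    stop("mcnemar_exact: inputs differ in length", call. = FALSE)
  b <- sum(correct_a & !correct_b)
  cc <- sum(!correct_a & correct_b)
  n <- b + cc
  if (n == 0)
    stop("mcnemar_exact: no discordant pairs, test undefined", call. = FALSE)
  p <- min(1, 2 * stats::pbinom(min(b, cc), n, 0.5))
  list(p_value = p, b = b, c = cc)
}
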