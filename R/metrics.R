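# Evaluation: confusion metrics, rank-statistic AUC, ROC, stratified split.

#' AUC by the rank statistic
#'
#' Mann-Whitney form with midranks for ties:
#' `(sum of positive ranks - n1 (n1 + 1) / 2) / (n1 n0)`.
#'
#' @param scores numeric scores, higher = more positive-like.
#' @param labels class labels.
#' @param positive positive-class label.
#' @return AUC in \[0, 1\], or `NA` if one class is absent.
#' @export
auc_rank <- function(scores, labels, positive) {
  pos <- labels == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)                 # midranks
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' One (FPR, TPR) point per distinct score threshold (descending), with the
#' (0, 0) and (1, 1) endpoints included; tied scores move along the diagonal
#' of their tie block, so trapezoidal integration reproduces the midrank AUC.
#'
#' @inheritParams auc_rank
#' @return data frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels, positive) {
  pos <- labels == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  th <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(th, function(s) sum(scores >= s & pos), numeric(1))
  fp <- vapply(th, function(s) sum(scores >= s & !pos), numeric(1))
  data.frame(threshold = c(Inf, th),
             fpr = c(0, fp / max(n0, 1)),
             tpr = c(0, tp / max(n1, 1)))
}

#' Confusion-based metrics and AUC for a binary classifier
#'
#' @param predictions predicted labels.
#' @param scores numeric scores used for the ROC/AUC.
#' @param labels true labels.
#' @param positive positive-class label (default `"malignant"`).
#' @return object of class `"metrics_report"`: accuracy, precision, recall,
#'   F1, AUC, confusion counts (tp, fp, tn, fn) and ROC points. AUC is `NA`
#'   when only one class is present.
#' @export
evaluate_classifier <- function(predictions, scores, labels,
                                positive = "malignant") {
  stopifnot(length(predictions) == length(labels),
            length(scores) == length(labels))
  pos <- labels == positive
  ppos <- predictions == positive
  tp <- sum(ppos & pos)
  fp <- sum(ppos & !pos)
  tn <- sum(!ppos & !pos)
  fn <- sum(!ppos & pos)
  accuracy <- (tp + tn) / length(labels)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  structure(list(accuracy = accuracy, precision = precision, recall = recall,
                 f1 = f1, auc = auc_rank(scores, labels, positive),
                 confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
                 roc = roc_points(scores, labels, positive),
                 positive = positive, n = length(labels)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Binary classification metrics (n = %d, positive = %s)\n",
              x$n, x$positive))
  cat(sprintf("  accuracy %.4f  precision %.4f  recall %.4f  F1 %.4f  AUC %s\n",
              x$accuracy, x$precision, x$recall, x$f1,
              ifelse(is.na(x$auc), "NA (single class)", sprintf("%.4f", x$auc))))
  cat(sprintf("  confusion: tp %d  fp %d  tn %d  fn %d\n",
              x$confusion["tp"], x$confusion["fp"],
              x$confusion["tn"], x$confusion["fn"]))
  invisible(x)
}

#' Seeded stratified train/test split
#'
#' Preserves per-class proportions within rounding: each class contributes
#' `floor(n_c * fraction)` training items, with the remainder (to reach
#' `round(n * fraction)` in total) assigned by largest fractional part (ties:
#' first class in sorted order). Every class keeps at least one item on each
#' side.
#'
#' @param labels class labels.
#' @param train_fraction fraction in (0, 1) (default 0.7).
#' @param seed seed for the within-class shuffles.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_dataset <- function(labels, train_fraction = 0.7, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie in (0, 1)")
  }
  lv <- sort(unique(labels))
  ncls <- vapply(lv, function(l) sum(labels == l), numeric(1))
  if (any(ncls < 2)) stop("every class needs at least 2 members")
  base <- floor(ncls * train_fraction)
  rem <- round(length(labels) * train_fraction) - sum(base)
  if (rem > 0) {
    fracs <- ncls * train_fraction - base
    extra <- order(-fracs, seq_along(lv))[seq_len(min(rem, length(lv)))]
    base[extra] <- base[extra] + 1
  }
  base <- pmin(pmax(base, 1), ncls - 1)
  train <- integer(0)
  with_seed(seed, {
    for (k in seq_along(lv)) {
      idx <- which(labels == lv[k])
      train <- c(train, sample(idx)[seq_len(base[k])])
    }
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}
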