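# Evaluation metrics: accuracy, F1 (positive class = high grade), AUC by
# rank-based ROC integration (Mann-Whitney with midranks for ties), and the
# 2x2 confusion matrix. Reported to 4 decimals (round half to even).

#' Classification metrics for one evaluation
#'
#' @param labels 0/1 vector (1 = high grade).
#' @param prob_high Predicted high-grade probabilities.
#' @param threshold Decision threshold on `prob_high`.
#' @return One-row tibble with `accuracy`, `f1`, `auc`, confusion counts
#'   `tp`/`fp`/`fn`/`tn` and `n`. With a single-class evaluation set the AUC
#'   is undefined and reported as `NA` with a warning.
#' @examples
#' metric_report(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
#'               c(.9, .8, .7, .4, .6, .2, .1, .3, .2, .1))
#' @export
metric_report <- function(labels, prob_high, threshold = 0.5) {
  stopifnot(length(labels) == length(prob_high))
  pred <- as.integer(prob_high > threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  n <- length(labels)
  accuracy <- (tp + tn) / n
  f1 <- if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  auc <- rank_auc(labels, prob_high)
  tibble::tibble(accuracy = round(accuracy, 4), f1 = round(f1, 4),
                 auc = round(auc, 4), tp = tp, fp = fp, fn = fn, tn = tn, n = n)
}

#' Rank-based AUC (Mann-Whitney statistic)
#' @export
rank_auc <- function(labels, scores) {
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    warning("single-class evaluation set: AUC undefined")
    return(NA_real_)
  }
  r <- rank(scores)                       # midranks for ties
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Aggregate per-fold metrics
#'
#' Arithmetic mean and population variance (division by the number of folds
#' k, not k - 1), each rounded to 4 decimals — the aggregation used for
#' k-fold cross-validation summaries.
#'
#' @param folds Tibble of per-fold metrics.
#' @param metrics Which columns to aggregate.
#' @return Tibble with one row per metric: `metric`, `mean`, `var`.
#' @export
aggregate_fold_metrics <- function(folds, metrics = c("accuracy", "f1", "auc")) {
  metrics <- intersect(metrics, names(folds))
  purrr::map_dfr(metrics, function(m) {
    v <- folds[[m]]
    v <- v[!is.na(v)]
    tibble::tibble(metric = m,
                   mean = round(mean(v), 4),
                   var = round(mean((v - mean(v))^2), 4))
  })
}
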