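# Evaluation suite: confusion counts, the five scalar diagnostics
# (sensitivity, specificity, precision, accuracy, Matthews correlation),
# and ROC/AUC by threshold sweep.

#' Confusion counts at a decision threshold
#'
#' A subject is predicted positive iff its score is greater than or equal to
#' the threshold.
#'
#' @param labels Binary labels (0/1).
#' @param scores Positive-class scores, one per label.
#' @param threshold Decision threshold (default 0.5).
#' @return A `confusion_counts` object with fields `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(labels) == 0L) abort("empty input.")
  if (length(labels) != length(scores)) abort("labels and scores differ in length.")
  pred <- as.integer(scores >= threshold)
  structure(list(
    tp = sum(pred == 1L & labels == 1L), tn = sum(pred == 0L & labels == 0L),
    fp = sum(pred == 1L & labels == 0L), fn = sum(pred == 0L & labels == 1L)
  ), class = "confusion_counts")
}

#' Scalar diagnostic metrics from confusion counts
#'
#' Computes sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, precision
#' `tp/(tp+fp)`, accuracy `(tp+tn)/total`, and the Matthews correlation
#' coefficient
#' `(tp*tn - fp*fn) / sqrt((tp+fn)(tp+fp)(tn+fn)(tn+fp))`.
#' Any metric with a zero denominator is defined as 0, so degenerate
#' cross-validation folds still aggregate.
#'
#' @param counts A `confusion_counts` object (or list with tp/tn/fp/fn).
#' @return A one-row tibble with columns `sn`, `sp`, `pre`, `acc`, `mcc`.
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  if (total <= 0) abort("confusion counts sum to zero.")
  safe_div <- function(num, den) if (den > 0) num / den else 0
  mcc_den <- sqrt(prod(c(tp + fn, tp + fp, tn + fn, tn + fp)))
  tibble::tibble(
    sn = safe_div(tp, tp + fn),
    sp = safe_div(tn, tn + fp),
    pre = safe_div(tp, tp + fp),
    acc = safe_div(tp + tn, total),
    mcc = if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else 0
  )
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the distinct score values as thresholds (equal scores grouped), and
#' integrates the curve by the trapezoid rule. Points run from (0, 0) to
#' (1, 1) and are nondecreasing in both coordinates.
#'
#' @param labels Binary labels with both classes present.
#' @param scores Positive-class scores.
#' @return A `roc_result`: `points` tibble (`fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
roc_curve_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) abort("both classes must be present for a ROC curve.")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  uniq <- !duplicated(s)
  grp_end <- c(which(uniq)[-1] - 1L, length(s))
  tp <- cumsum(y == 1L)[grp_end]
  fp <- cumsum(y == 0L)[grp_end]
  points <- tibble::tibble(
    fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos),
    threshold = c(Inf, s[uniq])
  )
  auc <- sum(diff(points$fpr) * (head(points$tpr, -1) + tail(points$tpr, -1)) / 2)
  structure(list(points = points, auc = auc), class = "roc_result")
}

auc_score <- function(labels, scores) roc_curve_auc(labels, scores)$auc

#' Full metrics report for scored subjects
#'
#' Bundles confusion counts, the five scalar metrics, and the ROC/AUC into
#' one object with [generics::tidy()], [generics::glance()] and
#' [ggplot2::autoplot()] methods.
#'
#' @inheritParams confusion_counts
#' @return A `metrics_report`.
#' @export
metrics_report <- function(labels, scores, threshold = 0.5) {
  counts <- confusion_counts(labels, scores, threshold)
  roc <- roc_curve_auc(labels, scores)
  structure(list(counts = counts, metrics = compute_metrics(counts),
                 roc = roc, threshold = threshold,
                 n = length(labels)), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  m <- glance(x)
  cat(sprintf(
    "<metrics_report> n=%d  acc=%.3f sn=%.3f sp=%.3f pre=%.3f mcc=%.3f auc=%.3f\n",
    x$n, m$acc, m$sn, m$sp, m$pre, m$mcc, m$auc))
  invisible(x)
}

#' @export
tidy.metrics_report <- function(x, ...) {
  tidyr::pivot_longer(glance(x), dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' @export
glance.metrics_report <- function(x, ...) {
  dplyr::bind_cols(
    x$metrics, tibble::tibble(
      auc = x$roc$auc, tp = x$counts$tp, tn = x$counts$tn,
      fp = x$counts$fp, fn = x$counts$fn, threshold = x$threshold))
}

#' @export
autoplot.metrics_report <- function(object, ...) {
  ggplot2::ggplot(object$roc$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2C7FB8") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$roc$auc)) +
    ggplot2::theme_minimal()
}

#' Serialize a metrics report to structured text (JSON)
#'
#' @param x A `metrics_report`.
#' @param path Target path.
#' @export
write_metrics <- function(x, path) {
  jsonlite::write_json(
    list(metrics = glance(x), roc_points = x$roc$points),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
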