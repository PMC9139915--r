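#' Average precision (area under the precision-recall curve)
#'
#' Step-summed AP: with thresholds descending over the unique scores (tied
#' scores form one threshold group, removing any order dependence),
#' `AP = sum_k (R_k - R_{k-1}) * P_k` where `P_k`/`R_k` are the precision and
#' recall after admitting the k-th score group. Equals the class prevalence
#' in expectation for uninformative scores.
#'
#' @param labels Binary labels (0/1) with at least one of each class.
#' @param scores Numeric classification scores (higher = more positive).
#' @return AP in `[0, 1]`.
#' @export
ap_score <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) .stopf("labels and scores differ in length")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) .stopf("AP needs at least one positive and one negative label")
  ord <- order(-scores, method = "radix")
  y <- labels[ord]; s <- scores[ord]
  ends <- cumsum(rle(s)$lengths)  # last index of each tied score group
  tp <- cumsum(y)[ends]
  prec <- tp / ends
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' ROC area under the curve
#'
#' Computed as the normalized Mann-Whitney rank statistic with the midrank
#' convention for tied scores (equivalent to trapezoidal integration of the
#' ROC curve).
#'
#' @inheritParams ap_score
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) .stopf("AUC needs at least one positive and one negative label")
  r <- rank(scores)  # midranks for ties
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Chance-level average precision
#'
#' The AP of a random classifier equals the positive fraction of the labels;
#' a model adds value only when its AP exceeds this baseline.
#'
#' @param labels Binary labels (non-empty, both classes present).
#' @return Positive fraction in `(0, 1)`.
#' @export
baseline_ap <- function(labels) {
  labels <- as.integer(labels)
  if (length(labels) == 0) .stopf("empty label vector")
  mean(labels == 1)
}

#' Precision-recall and ROC curve tables
#'
#' One point per descending unique-score threshold group.
#'
#' @inheritParams ap_score
#' @return `pr_curve()`: data frame `recall`, `precision` (recall
#'   non-decreasing); `roc_curve()`: data frame `fpr`, `tpr` including the
#'   (0,0) anchor.
#' @export
pr_curve <- function(labels, scores) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1)
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- t(vapply(thr, function(t) {
    sel <- scores >= t
    c(sum(labels[sel] == 1) / n_pos, sum(labels[sel] == 1) / sum(sel))
  }, c(0, 0)))
  data.frame(recall = pts[, 1], precision = pts[, 2])
}

#' @rdname pr_curve
#' @export
roc_curve <- function(labels, scores) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- t(vapply(thr, function(t) {
    sel <- scores >= t
    c(sum(labels[sel] == 0) / n_neg, sum(labels[sel] == 1) / n_pos)
  }, c(0, 0)))
  data.frame(fpr = c(0, pts[, 1]), tpr = c(0, pts[, 2]))
}

#' Evaluate probability scores against held-out labels
#'
#' Builds the full evaluation report for one model (or ensemble) on a test
#' subset: AP, ROC AUC, the PR and ROC curves, the chance baseline (test
#' prevalence), and the test counts.
#'
#' @inheritParams ap_score
#' @return An `evaluation_report` list: `ap`, `auc`, `pr_curve`, `roc_curve`,
#'   `baseline_ap`, `n_test`, `n_positive`.
#' @export
evaluate_scores <- function(labels, scores) {
  labels <- as.integer(labels)
  structure(list(ap = ap_score(labels, scores),
                 auc = roc_auc(labels, scores),
                 pr_curve = pr_curve(labels, scores),
                 roc_curve = roc_curve(labels, scores),
                 baseline_ap = baseline_ap(labels),
                 n_test = length(labels),
                 n_positive = sum(labels == 1)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> AP %.3f (chance %.3f), AUC %.3f, n = %d (%d positive)\n",
              x$ap, x$baseline_ap, x$auc, x$n_test, x$n_positive))
  invisible(x)
}

#' Serialize / restore an evaluation report
#'
#' JSON round trip is lossless (full double precision).
#' @param report An `evaluation_report`.
#' @param path JSON file path.
#' @export
write_evaluation_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_evaluation_report
#' @export
read_evaluation_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$pr_curve <- as.data.frame(x$pr_curve)
  x$roc_curve <- as.data.frame(x$roc_curve)
  structure(x, class = "evaluation_report")
}
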