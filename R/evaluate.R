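#' Confusion counts of binary predictions
#'
#' @param labels 0/1 vector of true labels (1 = positive).
#' @param predictions 0/1 vector of predicted labels, same length.
#' @return A one-row tibble with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(labels, predictions) {
  if (length(labels) != length(predictions)) {
    stop("confusion(): labels and predictions differ in length")
  }
  if (!length(labels)) stop("confusion(): empty input")
  stopifnot(all(labels %in% c(0, 1)), all(predictions %in% c(0, 1)))
  tibble::tibble(
    tp = sum(labels == 1 & predictions == 1),
    fp = sum(labels == 0 & predictions == 1),
    tn = sum(labels == 0 & predictions == 0),
    fn = sum(labels == 1 & predictions == 0)
  )
}

#' Scalar classification metrics from confusion counts
#'
#' Accuracy, sensitivity (recall), specificity, net prediction — the mean of
#' sensitivity and specificity, which is insensitive to class skew — and
#' precision. A metric whose denominator is zero is reported as `NA`
#' (explicitly undefined), never silently as 0 or 1.
#'
#' @param counts One-row tibble (or list) with `tp`, `fp`, `tn`, `fn`.
#' @return A one-row tibble with `accuracy`, `sensitivity`, `specificity`,
#'   `net_prediction`, `precision`.
#' @examples
#' psm_metrics(confusion(c(1, 0), c(1, 0)))
#' @export
psm_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  stopifnot(all(c(tp, fp, tn, fn) >= 0))
  total <- tp + fp + tn + fn
  if (total == 0) stop("psm_metrics(): no instances")
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  tibble::tibble(
    accuracy = (tp + tn) / total,
    sensitivity = sens,
    specificity = spec,
    net_prediction = (sens + spec) / 2,
    precision = safe_div(tp, tp + fp)
  )
}

# Threshold sweep shared by ROC and PRC: one step per distinct score,
# descending, with tied scores collapsed into a single step.
score_sweep <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  if (any(!is.finite(scores))) stop("non-finite scores")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  last_of_group <- c(s[-length(s)] != s[-1], TRUE)
  tibble::tibble(
    threshold = s[last_of_group],
    tp = cumsum(y == 1)[last_of_group],
    fp = cumsum(y == 0)[last_of_group]
  )
}

#' ROC curve and AUC
#'
#' Sweeps a threshold over every distinct score (instances scoring above the
#' threshold are called positive), producing the (1 - specificity,
#' sensitivity) curve anchored at (0, 0) and (1, 1). Tied scores are grouped
#' into a single threshold step, so ties contribute a diagonal segment and
#' the trapezoidal AUC equals the Mann-Whitney statistic with half credit
#' for ties.
#'
#' @param scores Numeric score vector (larger = more positive).
#' @param labels 0/1 vector, both classes present.
#' @return An object of class `psm_roc`: list with `points` (tibble `fpr`,
#'   `tpr`, `threshold`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  if (length(unique(labels)) < 2) {
    stop("roc_auc(): both classes must be present")
  }
  sw <- score_sweep(scores, labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  fpr <- c(0, sw$fp / n_neg)
  tpr <- c(0, sw$tp / n_pos)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(
    points = tibble::tibble(fpr = fpr, tpr = tpr,
                            threshold = c(Inf, sw$threshold)),
    auc = auc
  ), class = "psm_roc")
}

#' @export
print.psm_roc <- function(x, ...) {
  cat("ROC curve:", nrow(x$points), "points, AUC =",
      format(x$auc, digits = 5), "\n")
  invisible(x)
}

#' Precision-recall curve
#'
#' (recall, precision) at every distinct-score threshold of the same sweep
#' as [roc_auc()]; recall is non-decreasing along the sweep.
#'
#' @inheritParams roc_auc
#' @return An object of class `psm_prc`: list with `points` (tibble `recall`,
#'   `precision`, `threshold`).
#' @export
prc <- function(scores, labels) {
  if (!any(labels == 1)) stop("prc(): at least one positive is required")
  sw <- score_sweep(scores, labels)
  n_pos <- sum(labels == 1)
  structure(list(
    points = tibble::tibble(recall = sw$tp / n_pos,
                            precision = sw$tp / (sw$tp + sw$fp),
                            threshold = sw$threshold)
  ), class = "psm_prc")
}

#' @export
print.psm_prc <- function(x, ...) {
  cat("Precision-recall curve:", nrow(x$points), "points\n")
  invisible(x)
}

#' Full evaluation of scored instances
#'
#' Confusion-based scalar metrics at the stated decision rule (margin > 0,
#' or probability > 0.5 in calibrated mode) together with the ROC/AUC and
#' the precision-recall curve.
#'
#' @param data Tibble containing the score and label columns.
#' @param score Name of the score column.
#' @param label Name of the 0/1 label column.
#' @param threshold Decision threshold: instances with score strictly above
#'   it are called positive. Use 0 for margins, 0.5 for probabilities.
#' @return A list with `metrics` (one-row tibble including `auc`), `roc`
#'   (a `psm_roc`), and `prc` (a `psm_prc`).
#' @export
evaluate_psm <- function(data, score = "margin", label = "label",
                         threshold = 0) {
  stopifnot(score %in% names(data), label %in% names(data))
  s <- data[[score]]
  y <- data[[label]]
  roc <- roc_auc(s, y)
  pr <- prc(s, y)
  m <- psm_metrics(confusion(y, as.integer(s > threshold)))
  m$auc <- roc$auc
  list(metrics = m, roc = roc, prc = pr)
}

#' Plot a ROC curve
#'
#' @param object A `psm_roc` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.psm_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate (1 - specificity)",
                  y = "Sensitivity",
                  title = sprintf("ROC (AUC = %.4f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot a precision-recall curve
#'
#' @param object A `psm_prc` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.psm_prc <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision",
                  title = "Precision-recall curve") +
    ggplot2::theme_minimal()
}
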