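#' ROC analysis of discriminant scores
#'
#' Sweeps every achievable decision threshold — the midpoints between
#' adjacent sorted unique scores plus `-Inf`/`+Inf` sentinels — and
#' records sensitivity and specificity of the rule `score >= threshold
#' => positive`.  The operating cutoff is the threshold maximising
#' Youden's J (`sensitivity + specificity - 1`); ties are broken toward
#' the candidate nearest the pooled score median.  The area under the
#' curve is computed by the Mann-Whitney pair-count identity (ties count
#' one half).
#'
#' @param scores Numeric score per subject.
#' @param labels Binary labels (1 = positive class) aligned with
#'   `scores`.
#' @return Object of class `wtx_roc`: list with `curve` (tibble of
#'   `threshold`, `sensitivity`, `specificity`, `youden_j`), `auc`,
#'   `best_cutoff`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' r <- roc_analysis(c(1, 2, 3, -2, -1), c(1, 1, 1, 0, 0))
#' r$auc          # 1
#' r$best_cutoff  # 0
roc_analysis <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels)) {
    stop("scores and labels must align and contain no missing values",
         call. = FALSE)
  }
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("both classes must be present for ROC analysis", call. = FALSE)
  }
  su <- sort(unique(scores))
  thresholds <- c(-Inf, if (length(su) > 1L) (su[-1L] + su[-length(su)]) / 2,
                  Inf)
  sens <- vapply(thresholds, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(neg < t), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))
  if (length(best) > 1L) {
    med <- stats::median(scores)
    best <- best[which.min(abs(thresholds[best] - med))]
  }
  auc <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  structure(list(
    curve = tibble::tibble(threshold = thresholds, sensitivity = sens,
                           specificity = spec, youden_j = j),
    auc = auc,
    best_cutoff = thresholds[best],
    n_pos = length(pos), n_neg = length(neg)
  ), class = "wtx_roc")
}

#' @export
print.wtx_roc <- function(x, ...) {
  cat("<wtx_roc: ", x$n_pos, " positive vs ", x$n_neg, " negative>\n",
      "  AUC ", format(x$auc, digits = 4),
      ", best cutoff ", format(x$best_cutoff, digits = 6),
      " (Youden J ", format(max(x$curve$youden_j), digits = 4), ")\n",
      sep = "")
  invisible(x)
}

#' Confusion metrics at a decision cutoff
#'
#' Classifies `score >= cutoff` as positive and tabulates the 2x2
#' confusion counts with the five standard proportions.  PPV/NPV are
#' `NA` when no subject is predicted in the corresponding class.
#'
#' @inheritParams roc_analysis
#' @param cutoff Decision threshold.
#' @return One-row tibble: `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `accuracy`, `ppv`, `npv`.
#' @export
#' @examples
#' confusion_metrics(c(2, 1, 3, -1, 0.5, -2), c(1, 1, 1, 0, 0, 0), 0.2)
confusion_metrics <- function(scores, labels, cutoff) {
  labels <- as.integer(as.logical(labels))
  if (!any(labels == 1L) || !any(labels == 0L)) {
    stop("both classes must be present", call. = FALSE)
  }
  predicted <- as.integer(scores >= cutoff)
  .confusion_from_predictions(predicted, labels)
}

.confusion_from_predictions <- function(predicted, labels) {
  tp <- sum(predicted == 1L & labels == 1L)
  fp <- sum(predicted == 1L & labels == 0L)
  tn <- sum(predicted == 0L & labels == 0L)
  fn <- sum(predicted == 0L & labels == 1L)
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = div(tp, tp + fn),
    specificity = div(tn, tn + fp),
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    ppv = div(tp, tp + fp),
    npv = div(tn, tn + fn))
}
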