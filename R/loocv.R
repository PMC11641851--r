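#' Leave-one-out cross-validation of the discriminant pipeline
#'
#' For each subject in turn: refit the discriminant on the remaining
#' `n - 1` subjects (optionally rerunning the stepwise feature
#' selection inside the fold), choose the Youden-optimal cutoff on the
#' training scores, and classify the held-out subject by
#' `DS >= cutoff`.  The held-out subject never influences its own
#' fold's model.
#'
#' The default keeps the feature set fixed across folds and refits only
#' the coefficients and cutoff, matching the leave-one-out
#' classification convention of mainstream discriminant software;
#' `refit_selection = TRUE` reruns [stepwise_select()] per fold, the
#' statistically stricter variant (a fold with an empty selection
#' predicts its training majority class).
#'
#' @param table Feature table; at least 6 subjects with 3 per class.
#' @param features Feature names used in every fold (required unless
#'   `refit_selection = TRUE`).
#' @param refit_selection Rerun stepwise selection inside each fold.
#' @param f_enter,f_remove Stepwise thresholds, when refitting
#'   selection.
#' @return Object of class `wtx_loocv`: list with `predictions` (tibble
#'   of `subject_id`, `label`, `ds`, `predicted` — exactly one held-out
#'   row per subject), `metrics` (one-row [confusion_metrics()] tibble
#'   over the held-out predictions), and `n_folds`.
#' @export
loocv <- function(table, features = NULL, refit_selection = FALSE,
                  f_enter = 3.84, f_remove = 2.71) {
  .check_feature_table(table)
  n <- nrow(table)
  n_pos <- sum(table$label == 1L)
  n_neg <- n - n_pos
  if (n < 6L || n_pos < 3L || n_neg < 3L) {
    stop("leave-one-out needs n >= 6 with at least 3 subjects per class",
         call. = FALSE)
  }
  if (!refit_selection && is.null(features)) {
    stop("supply `features`, or set refit_selection = TRUE", call. = FALSE)
  }
  folds <- purrr::map(seq_len(n), function(i) {
    train <- table[-i, , drop = FALSE]
    if (length(unique(train$label)) < 2L) {
      stop("fold ", i, " lost an entire class", call. = FALSE)
    }
    feats <- features
    if (refit_selection) {
      feats <- stepwise_select(train, f_enter = f_enter,
                               f_remove = f_remove)$selected
      if (length(feats) == 0L) {
        majority <- as.integer(mean(train$label) >= 0.5)
        return(tibble::tibble(subject_id = table$subject_id[i],
                              label = table$label[i],
                              ds = NA_real_, predicted = majority))
      }
    }
    fit <- fit_lda(train, feats)
    ds_i <- score(fit, table[i, , drop = FALSE])
    tibble::tibble(subject_id = table$subject_id[i],
                   label = table$label[i],
                   ds = ds_i,
                   predicted = as.integer(ds_i >= fit$cutoff))
  })
  predictions <- dplyr::bind_rows(folds)
  structure(list(
    predictions = predictions,
    metrics = .confusion_from_predictions(predictions$predicted,
                                          predictions$label),
    n_folds = n,
    refit_selection = refit_selection
  ), class = "wtx_loocv")
}

#' @export
print.wtx_loocv <- function(x, ...) {
  m <- x$metrics
  cat("<wtx_loocv: ", x$n_folds, " folds",
      if (x$refit_selection) ", selection refit per fold", ">\n",
      "  accuracy ", format(m$accuracy, digits = 4),
      ", sensitivity ", format(m$sensitivity, digits = 4),
      ", specificity ", format(m$specificity, digits = 4), "\n",
      sep = "")
  invisible(x)
}
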