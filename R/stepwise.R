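#' Forward-stepwise feature selection by Wilks' lambda
#'
#' Classic stepwise discriminant selection: at each step the candidate
#' whose entry most reduces Wilks' lambda (ratio of within-group to
#' total generalised variance) is admitted if its partial F-to-enter
#' exceeds `f_enter`; after every entry, already-selected features whose
#' F-to-remove has fallen below `f_remove` are dropped.  The F floors
#' default to the conventional discriminant-analysis thresholds
#' (F-to-enter 3.84, F-to-remove 2.71).  Selection is fully
#' deterministic given the table.
#'
#' With many more candidate features than subjects the classic floors
#' degenerate: the largest of a hundred null partial-F statistics
#' exceeds 3.84 almost surely, so noise features chain-enter up to the
#' feature cap.  Setting `alpha_enter` additionally gates entry by a
#' Bonferroni-adjusted critical value,
#' `qf(1 - alpha_enter / m, 1, n - 2 - p)` with `m` the number of
#' candidates tested at that step, holding the family-wise false-entry
#' level at `alpha_enter` however many features compete.  The gate keeps
#' null selections empty but is necessarily conservative for
#' redundant-signal features (the partial F of a feature duplicating an
#' already-selected discriminant direction saturates near `n - 2 - p`,
#' i.e. near the adjusted critical value, whatever the effect size).
#' The default (`NULL`) is the classic ungated procedure, which is what
#' the reference analysis mode prescribes.
#'
#' Candidates whose entry would make the within-group matrix numerically
#' singular are skipped (tolerance on the lambda denominator), so
#' collinear duplicates of selected features are never admitted.
#'
#' @param table Feature table with `label` and feature columns; at least
#'   4 subjects per class.
#' @param f_enter,f_remove Partial F thresholds; `f_remove` must be
#'   below `f_enter`.
#' @param alpha_enter Optional family-wise significance level of the
#'   Bonferroni-adjusted entry gate; `NULL` (default) disables the gate.
#' @param max_features Cap on the selected-set size (default keeps the
#'   fit well-determined at `n - 3`).
#' @return Object of class `wtx_stepwise`: list with `selected`
#'   (character vector, possibly empty) and `trace`, a tibble recording
#'   each step's action, feature, partial F and resulting Wilks' lambda.
#' @export
stepwise_select <- function(table, f_enter = 3.84, f_remove = 2.71,
                            alpha_enter = NULL, max_features = NULL) {
  .check_feature_table(table)
  y <- table$label
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  if (n_pos < 4L || n_neg < 4L) {
    stop("stepwise selection needs at least 4 subjects per class",
         call. = FALSE)
  }
  if (f_remove >= f_enter) {
    stop("f_remove must be below f_enter", call. = FALSE)
  }
  feats <- feature_columns(table)
  n <- length(y)
  if (is.null(max_features)) max_features <- n - 3L
  X <- as.matrix(table[feats])
  # total and within-group cross-product matrices over all features
  Tm <- crossprod(scale(X, center = TRUE, scale = FALSE))
  Wm <- crossprod(scale(X[y == 1L, , drop = FALSE], center = TRUE,
                        scale = FALSE)) +
        crossprod(scale(X[y == 0L, , drop = FALSE], center = TRUE,
                        scale = FALSE))
  tol <- 1e-10
  lambda_of <- function(idx) {
    if (length(idx) == 0L) return(1)
    dT <- det(Tm[idx, idx, drop = FALSE])
    dW <- det(Wm[idx, idx, drop = FALSE])
    if (!is.finite(dT) || !is.finite(dW) || dT <= tol * max(1, abs(dW))) {
      return(NA_real_)
    }
    lam <- dW / dT
    if (!is.finite(lam) || lam <= 0) NA_real_ else lam
  }
  selected <- integer(0)
  lam_cur <- 1
  trace <- list()
  note <- function(action, feature, f, lam) {
    trace[[length(trace) + 1L]] <<- tibble::tibble(
      step = length(trace) + 1L, action = action, feature = feature,
      partial_f = f, wilks_lambda = lam)
  }
  repeat {
    if (length(selected) >= max_features) {
      note("stop", NA_character_, NA_real_, lam_cur)
      break
    }
    p <- length(selected)
    cand <- setdiff(seq_along(feats), selected)
    f_vals <- vapply(cand, function(v) {
      lam_new <- lambda_of(c(selected, v))
      if (is.na(lam_new) || lam_new >= lam_cur || lam_new <= 0) {
        return(NA_real_)
      }
      ratio <- lam_new / lam_cur
      (n - 2 - p) * (1 - ratio) / ratio
    }, numeric(1))
    f_crit <- f_enter
    if (!is.null(alpha_enter)) {
      m <- sum(!is.na(f_vals))
      if (m > 0L) {
        f_crit <- max(f_enter,
                      stats::qf(1 - alpha_enter / m, 1, n - 2 - p))
      }
    }
    if (all(is.na(f_vals)) || max(f_vals, na.rm = TRUE) < f_crit) {
      note("stop", NA_character_,
           if (all(is.na(f_vals))) NA_real_ else max(f_vals, na.rm = TRUE),
           lam_cur)
      break
    }
    best <- cand[which.max(f_vals)]
    lam_cur <- lambda_of(c(selected, best))
    selected <- c(selected, best)
    note("add", feats[best], max(f_vals, na.rm = TRUE), lam_cur)
    # backward pass: drop features whose contribution has decayed
    repeat {
      if (length(selected) < 2L) break
      p <- length(selected)
      f_rem <- vapply(seq_along(selected), function(k) {
        lam_wo <- lambda_of(selected[-k])
        if (is.na(lam_wo)) return(Inf)
        ratio <- lam_cur / lam_wo
        (n - 1 - p) * (1 - ratio) / ratio
      }, numeric(1))
      k <- which.min(f_rem)
      if (f_rem[k] >= f_remove || selected[k] == selected[length(selected)]) {
        break
      }
      dropped <- selected[k]
      selected <- selected[-k]
      lam_cur <- lambda_of(selected)
      note("remove", feats[dropped], f_rem[k], lam_cur)
    }
  }
  structure(list(
    selected = feats[selected],
    trace = dplyr::bind_rows(trace),
    f_enter = f_enter, f_remove = f_remove
  ), class = "wtx_stepwise")
}

#' @export
print.wtx_stepwise <- function(x, ...) {
  cat("<wtx_stepwise: ", length(x$selected), " feature(s) selected>\n",
      sep = "")
  if (length(x$selected)) {
    cat("  ", paste(x$selected, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
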