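#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted discriminant model
#'
#' @param x A `wtx_lda`.
#' @param ... Unused.
#' @return Tibble with one row per model term (the constant first):
#'   `term`, `estimate`.
#' @method tidy wtx_lda
#' @export
tidy.wtx_lda <- function(x, ...) {
  tibble::tibble(term = c("(constant)", x$features),
                 estimate = c(x$constant, unname(x$coefficients)))
}

#' @rdname tidy.wtx_lda
#' @return `glance()`: one-row tibble with `n_features`, `cutoff`,
#'   `n_pos`, `n_neg` and the class score means (when fitted in
#'   session; the serialised reference fixture carries no training
#'   scores).
#' @method glance wtx_lda
#' @export
glance.wtx_lda <- function(x, ...) {
  tibble::tibble(n_features = length(x$features),
                 cutoff = x$cutoff,
                 n_pos = x$n_pos %||% NA_integer_,
                 n_neg = x$n_neg %||% NA_integer_,
                 score_mean_pos = x$score_mean_pos %||% NA_real_,
                 score_mean_neg = x$score_mean_neg %||% NA_real_)
}

#' Tidy an ROC analysis
#'
#' @param x A `wtx_roc`.
#' @param ... Unused.
#' @return `tidy()`: the threshold sweep tibble; `glance()`: one row
#'   with `auc`, `best_cutoff`, `youden_j`, `n_pos`, `n_neg`.
#' @method tidy wtx_roc
#' @export
tidy.wtx_roc <- function(x, ...) x$curve

#' @rdname tidy.wtx_roc
#' @method glance wtx_roc
#' @export
glance.wtx_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, best_cutoff = x$best_cutoff,
                 youden_j = max(x$curve$youden_j),
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Tidy a leave-one-out result
#'
#' @param x A `wtx_loocv`.
#' @param ... Unused.
#' @return `tidy()`: per-subject held-out predictions; `glance()`: the
#'   one-row confusion-metrics tibble.
#' @method tidy wtx_loocv
#' @export
tidy.wtx_loocv <- function(x, ...) x$predictions

#' @rdname tidy.wtx_loocv
#' @method glance wtx_loocv
#' @export
glance.wtx_loocv <- function(x, ...) x$metrics

#' Plot an ROC curve
#'
#' @param object A `wtx_roc`.
#' @param ... Unused.
#' @return A ggplot: ROC curve in (1 - specificity, sensitivity) space
#'   with the Youden-optimal operating point marked.
#' @method autoplot wtx_roc
#' @export
autoplot.wtx_roc <- function(object, ...) {
  d <- dplyr::arrange(object$curve, dplyr::desc(.data$threshold))
  best <- object$curve[which(object$curve$threshold ==
                               object$best_cutoff)[1], ]
  ggplot2::ggplot(d, ggplot2::aes(1 - .data$specificity,
                                  .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point(data = best, colour = "red", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("ROC (AUC = %.3f)", object$auc),
                  subtitle = sprintf("Youden cutoff %.4f",
                                     object$best_cutoff)) +
    ggplot2::theme_minimal()
}

#' Plot discriminant scores by class
#'
#' Dot plot of per-subject discriminant scores split by true class with
#' the decision cutoff drawn as a horizontal line.
#'
#' @param model A `wtx_lda` fitted in session (with training scores),
#'   or any tibble with `label` and `ds` columns via `scores`.
#' @param scores Optional tibble of `label`/`ds` overriding the model's
#'   training scores.
#' @return A ggplot.
#' @export
plot_scores <- function(model, scores = NULL) {
  if (is.null(scores)) {
    if (is.null(model$training)) {
      stop("model carries no training scores; supply `scores`",
           call. = FALSE)
    }
    scores <- model$training
  }
  d <- dplyr::mutate(scores, class = factor(
    .data$label, levels = c(1, 0),
    labels = c("positive (responder)", "negative")))
  ggplot2::ggplot(d, ggplot2::aes(.data$class, .data$ds)) +
    ggplot2::geom_hline(yintercept = model$cutoff, linetype = "dashed",
                        colour = "red") +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.8) +
    ggplot2::labs(x = NULL, y = "discriminant score (DS)",
                  subtitle = sprintf("cutoff %.4f", model$cutoff)) +
    ggplot2::theme_minimal()
}

#' Display a grayscale image
#'
#' @param image A [gray_image()].
#' @param show_mask Outline the ROI mask, when present.
#' @return A ggplot raster of the pixel matrix.
#' @export
plot_image <- function(image, show_mask = TRUE) {
  stopifnot(inherits(image, "gray_image"))
  d <- tidyr::expand_grid(row = seq_len(nrow(image$pixels)),
                          col = seq_len(ncol(image$pixels)))
  d$value <- as.vector(t(image$pixels))
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$col, .data$row,
                                       fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "gray")
  if (show_mask && !is.null(image$mask)) {
    d$mask <- as.vector(t(image$mask))
    p <- p + ggplot2::geom_contour(
      data = d, ggplot2::aes(z = as.numeric(.data$mask)),
      breaks = 0.5, colour = "red", linewidth = 0.3)
  }
  p
}
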