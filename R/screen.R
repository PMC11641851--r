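#' Lilliefors-corrected Kolmogorov-Smirnov normality test
#'
#' One-sample KS statistic against a normal distribution whose mean and
#' standard deviation are estimated from the sample, with the Lilliefors
#' p-value correction that accounts for the estimated parameters.
#'
#' @param sample Numeric vector, `n >= 4`, non-degenerate.
#' @return One-row tibble with `statistic`, `p` and `n`.
#' @export
ks_normality <- function(sample) {
  sample <- as.numeric(sample)
  if (length(sample) < 4L) {
    stop("normality test needs n >= 4, got ", length(sample), call. = FALSE)
  }
  if (!all(is.finite(sample))) stop("non-finite values", call. = FALSE)
  if (stats::sd(sample) == 0) {
    stop("degenerate (constant) sample: normality test undefined",
         call. = FALSE)
  }
  res <- nortest::lillie.test(sample)
  tibble::tibble(statistic = unname(res$statistic),
                 p = unname(res$p.value),
                 n = length(sample))
}

.group_summary <- function(mean, sd, n) {
  if (n < 2L || n != round(n)) stop("group n must be an integer >= 2",
                                    call. = FALSE)
  if (sd < 0) stop("sd must be nonnegative", call. = FALSE)
  list(mean = mean, sd = sd, n = as.integer(n))
}

#' Two-sample t-test from group summary statistics
#'
#' Computes the Welch (unequal-variance, Satterthwaite degrees of
#' freedom) or pooled (classic Student) two-sample t-test directly from
#' per-group means, standard deviations and sizes — the form needed to
#' reanalyse published summary tables.
#'
#' @param mean1,sd1,n1 Summary of the first group (sample SD, `n >= 2`).
#' @param mean2,sd2,n2 Summary of the second group.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return One-row tibble with `t`, `df`, `p` (two-tailed) and
#'   `variant`.
#' @export
#' @examples
#' # group summaries of a strongly separated feature
#' ttest_from_summary(866.46, 1.86, 7, 860.27, 5.51, 15)
ttest_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                               variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  g1 <- .group_summary(mean1, sd1, n1)
  g2 <- .group_summary(mean2, sd2, n2)
  if (g1$sd == 0 && g2$sd == 0) {
    stop("zero variance in both groups: t-test undefined", call. = FALSE)
  }
  if (variant == "welch") {
    v1 <- g1$sd^2 / g1$n
    v2 <- g2$sd^2 / g2$n
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (g1$n - 1) + v2^2 / (g2$n - 1))
  } else {
    sp2 <- ((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) /
      (g1$n + g2$n - 2)
    se <- sqrt(sp2 * (1 / g1$n + 1 / g2$n))
    df <- g1$n + g2$n - 2
  }
  t <- (g1$mean - g2$mean) / se
  tibble::tibble(t = t, df = df,
                 p = 2 * stats::pt(-abs(t), df),
                 variant = variant)
}

#' Two-sample t-test on raw samples
#'
#' Thin consistency wrapper: summarises each sample and delegates to
#' [ttest_from_summary()], so the raw and summary forms agree exactly on
#' shared inputs.
#'
#' @param x1,x2 Numeric samples with `n >= 2` each.
#' @inheritParams ttest_from_summary
#' @return One-row tibble as in [ttest_from_summary()].
#' @export
ttest_raw <- function(x1, x2, variant = c("welch", "pooled")) {
  if (length(x1) < 2L || length(x2) < 2L) {
    stop("each sample needs n >= 2", call. = FALSE)
  }
  ttest_from_summary(mean(x1), stats::sd(x1), length(x1),
                     mean(x2), stats::sd(x2), length(x2),
                     variant = match.arg(variant))
}

#' Univariate screening of every feature between the two classes
#'
#' Per-feature two-sample comparison of positive (label 1) against
#' negative (label 0) subjects.  The report is descriptive and does not
#' gate the multivariate stage: features are flagged into significance
#' tiers (`p <= 0.05`, `p <= 0.15` "near", otherwise `ns`) and sorted by
#' p-value.  Zero-variance features are reported as untestable
#' (`NA` statistics, tier `degenerate`) rather than dropped.
#' A Bonferroni-adjusted column is appended as an optional extra; no
#' multiplicity correction is part of the screening decision itself.
#'
#' @param table Feature table from [extract_cohort()] (or
#'   [generate_feature_cohort()]).
#' @inheritParams ttest_from_summary
#' @return Tibble with one row per feature: group means/SDs/sizes, `t`,
#'   `df`, `p`, `p_bonferroni`, and `tier`.
#' @export
univariate_screen <- function(table, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  .check_feature_table(table)
  if (length(unique(table$label)) < 2L) {
    stop("both classes must be present for screening", call. = FALSE)
  }
  feats <- feature_columns(table)
  pos <- table[table$label == 1L, , drop = FALSE]
  neg <- table[table$label == 0L, , drop = FALSE]
  res <- purrr::map_dfr(feats, function(f) {
    x1 <- pos[[f]]
    x2 <- neg[[f]]
    base <- tibble::tibble(
      feature = f,
      mean_pos = mean(x1), sd_pos = stats::sd(x1), n_pos = length(x1),
      mean_neg = mean(x2), sd_neg = stats::sd(x2), n_neg = length(x2))
    tt <- tryCatch(ttest_raw(x1, x2, variant = variant),
                   error = function(e) NULL)
    if (is.null(tt)) {
      dplyr::mutate(base, t = NA_real_, df = NA_real_, p = NA_real_)
    } else {
      dplyr::bind_cols(base, tt[c("t", "df", "p")])
    }
  })
  res <- dplyr::mutate(res,
    p_bonferroni = pmin(1, .data$p * length(feats)),
    tier = dplyr::case_when(
      is.na(.data$p) ~ "degenerate",
      .data$p <= 0.05 ~ "p<=0.05",
      .data$p <= 0.15 ~ "near (p<=0.15)",
      TRUE ~ "ns"))
  dplyr::arrange(res, is.na(.data$p), .data$p)
}
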