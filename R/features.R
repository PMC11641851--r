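#' Names of the 120 wavelet-texture features
#'
#' Deterministic feature ordering: for each wavelet (in
#' [wavetex_wavelets()] order), for each decomposition level 1..3, the
#' four statistics `mn` (mean), `md` (median), `max` (signed maximum)
#' and `sd` (sample standard deviation), named
#' `"{wavelet}dec{level}{stat}"` — e.g. `db2dec2sd`, `bior33dec1max`.
#'
#' @param wavelets Wavelet identifiers (default all ten).
#' @param levels Number of decomposition levels (default 3).
#' @param stats Statistic suffixes (default the four above).
#' @return Character vector of feature names
#'   (`length(wavelets) * levels * length(stats)` entries; 120 at the
#'   defaults).
#' @export
#' @examples
#' length(feature_names())  # 120
feature_names <- function(wavelets = wavetex_wavelets(), levels = 3L,
                          stats = c("mn", "md", "max", "sd")) {
  as.vector(vapply(wavelets, function(w) {
    as.vector(vapply(seq_len(levels), function(l) {
      paste0(w, "dec", l, stats)
    }, character(length(stats))))
  }, character(levels * length(stats))))
}

#' Summary statistics of a coefficient matrix
#'
#' The four per-subband summaries used as texture variables: arithmetic
#' mean, median (mean of the two central order statistics for even
#' counts), signed maximum, and sample standard deviation (`n - 1`
#' denominator).
#'
#' @param coeffs Numeric matrix (or vector) of at least 2 finite values.
#' @return One-row [tibble::tibble] with columns `mn`, `md`, `max`, `sd`.
#' @export
#' @examples
#' coefficient_stats(c(1, 2, 3, 4))  # mn 2.5, md 2.5, max 4, sd 1.29
coefficient_stats <- function(coeffs) {
  v <- as.vector(coeffs)
  if (length(v) < 2L) {
    stop("coefficient_stats needs at least 2 values (sd undefined)",
         call. = FALSE)
  }
  if (!all(is.finite(v))) {
    stop("coefficients contain non-finite values", call. = FALSE)
  }
  tibble::tibble(mn = mean(v), md = stats::median(v),
                 max = max(v), sd = stats::sd(v))
}

#' Extract the wavelet-texture feature vector of one image
#'
#' Decomposes the ROI crop of `image` to `levels` dyadic levels with
#' each requested wavelet and summarises one subband per level with
#' [coefficient_stats()].  By default the statistics are taken over the
#' approximation (low-pass) coefficients at each level, whose DC-gain
#' scaling matches the magnitudes these features are known by; setting
#' `subband = "detail"` instead pools the three detail subbands at each
#' level, for sensitivity analysis.
#'
#' @param image A [gray_image()]; masked images are cropped with
#'   [crop_to_roi()] first.
#' @param wavelets Wavelet identifiers (default all ten).
#' @param levels Decomposition depth (default 3).
#' @param subband `"approximation"` (default) or `"detail"`.
#' @return One-row tibble with `subject_id` plus one column per feature
#'   (120 at the defaults), in [feature_names()] order; all values
#'   finite.
#' @export
extract_features <- function(image, wavelets = wavetex_wavelets(),
                             levels = 3L,
                             subband = c("approximation", "detail")) {
  stopifnot(inherits(image, "gray_image"))
  subband <- match.arg(subband)
  image <- crop_to_roi(image)
  px <- image$pixels
  vals <- unlist(lapply(wavelets, function(w) {
    pyr <- tryCatch(
      wavedec2(px, w, levels),
      error = function(e) {
        stop("feature extraction failed for subject '",
             image$subject_id %||% "<unnamed>", "': ",
             conditionMessage(e), call. = FALSE)
      }
    )
    unlist(lapply(seq_len(levels), function(l) {
      sb <- pyr$levels[[l]]
      co <- if (subband == "approximation") sb$cA else c(sb$cH, sb$cV, sb$cD)
      s <- coefficient_stats(co)
      c(s$mn, s$md, s$max, s$sd)
    }))
  }))
  names(vals) <- feature_names(wavelets, levels)
  out <- tibble::as_tibble(as.list(vals))
  tibble::add_column(out,
                     subject_id = image$subject_id %||% NA_character_,
                     .before = 1L)
}

#' Extract a cohort-level feature table
#'
#' Row-binds [extract_features()] across subjects and attaches the
#' binary class label (1 = responder / positive class, 0 = negative).
#'
#' @param images List of [gray_image()] objects with distinct
#'   `subject_id`s.
#' @param labels Vector of 0/1 (or logical) labels aligned with
#'   `images`.
#' @inheritParams extract_features
#' @return Tibble with columns `subject_id`, `label`, and one column per
#'   feature; one row per subject.
#' @export
extract_cohort <- function(images, labels, wavelets = wavetex_wavelets(),
                           levels = 3L,
                           subband = c("approximation", "detail")) {
  subband <- match.arg(subband)
  if (length(images) == 0L) stop("empty image list", call. = FALSE)
  if (length(labels) != length(images)) {
    stop("labels (", length(labels), ") do not align with images (",
         length(images), ")", call. = FALSE)
  }
  labels <- as.integer(as.logical(labels))
  if (anyNA(labels)) stop("labels must be binary 0/1", call. = FALSE)
  ids <- vapply(images, function(im) im$subject_id %||% NA_character_,
                character(1))
  if (anyNA(ids)) stop("every image needs a subject_id", call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicate subject_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  rows <- purrr::map(images, extract_features, wavelets = wavelets,
                     levels = levels, subband = subband)
  tab <- dplyr::bind_rows(rows)
  tibble::add_column(tab, label = labels, .after = "subject_id")
}

#' Feature columns of a feature table
#'
#' Everything except the `subject_id`/`label` metadata columns.
#'
#' @param table A feature table.
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(table) {
  setdiff(names(table), c("subject_id", "label"))
}

.check_feature_table <- function(table, need_labels = TRUE) {
  if (!is.data.frame(table) || !"subject_id" %in% names(table)) {
    stop("expected a feature table with a subject_id column", call. = FALSE)
  }
  if (need_labels) {
    if (!"label" %in% names(table)) {
      stop("feature table has no label column", call. = FALSE)
    }
    if (!all(table$label %in% c(0L, 1L))) {
      stop("labels must be binary 0/1", call. = FALSE)
    }
  }
  invisible(table)
}

#' Read/write feature tables as CSV
#'
#' Plain comma-separated text with a header row
#' `subject_id,label,<feature names>`; values are printed at full double
#' precision so byte-identical reruns can be verified.
#'
#' @param table Feature table tibble.
#' @param path CSV file path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns the tibble.
#' @export
write_feature_table <- function(table, path) {
  .check_feature_table(table, need_labels = "label" %in% names(table))
  out <- dplyr::mutate(table, dplyr::across(
    dplyr::where(is.double), ~ sprintf("%.17g", .x)))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  # base read.csv parses doubles correctly rounded, so the 17-digit
  # representation written above round-trips bit-exactly
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  if ("label" %in% names(df)) df$label <- as.integer(df$label)
  tibble::as_tibble(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
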