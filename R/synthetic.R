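#' Texture parameters of one synthetic tumor class
#'
#' Parameters of the Gaussian-random-field texture model used by the
#' synthetic cohort generator.  Units are 8-bit gray levels except
#' `correlation_length` (pixels).
#'
#' @param base_intensity Mean gray level of the tumor interior.
#' @param contrast Standard deviation of the smooth textured component.
#' @param correlation_length Gaussian smoothing scale of the texture, in
#'   pixels.
#' @param noise_sd Additive white-noise standard deviation.
#' @return Object of class `class_texture_params`.
#' @export
class_texture_params <- function(base_intensity = 120, contrast = 30,
                                 correlation_length = 3, noise_sd = 10) {
  stopifnot(base_intensity > 0, base_intensity < 255,
            contrast >= 0, correlation_length >= 0, noise_sd >= 0)
  structure(list(base_intensity = base_intensity, contrast = contrast,
                 correlation_length = correlation_length,
                 noise_sd = noise_sd), class = "class_texture_params")
}

#' Configuration of a two-class synthetic image cohort
#'
#' Defaults mirror the study conditions the package is exercised under:
#' 7 positive (complete-response) and 15 negative subjects, 64x64-pixel
#' ROIs.  The positive class actually generated interpolates between the
#' negative-class parameters (`effect = 0`, identical classes) and
#' `params_pos` (`effect = 1`); at the default parameters `effect = 1`
#' corresponds to a 30-gray-level shift in base intensity, many times
#' the between-subject spread of the mean-intensity features, i.e. a
#' strongly separated cohort.
#'
#' @param n_pos,n_neg Class sizes (each at least 3).
#' @param image_size Pixels per side.
#' @param params_pos,params_neg Class texture parameters
#'   ([class_texture_params()]).
#' @param effect Interpolation scalar `params_neg -> params_pos`
#'   (0 = identical classes).
#' @param seed Integer master seed; per-subject child seeds are derived
#'   deterministically from it.
#' @return Object of class `synthetic_cohort_config`.
#' @export
cohort_config <- function(n_pos = 7L, n_neg = 15L, image_size = 64L,
                          params_pos = class_texture_params(
                            base_intensity = 150),
                          params_neg = class_texture_params(),
                          effect = 1, seed = 1L) {
  stopifnot(n_pos >= 3L, n_neg >= 3L, image_size >= 16L, effect >= 0)
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 image_size = as.integer(image_size),
                 params_pos = params_pos, params_neg = params_neg,
                 effect = effect, seed = as.integer(seed)),
            class = "synthetic_cohort_config")
}

.interp_params <- function(neg, pos, effect) {
  class_texture_params(
    base_intensity = neg$base_intensity +
      effect * (pos$base_intensity - neg$base_intensity),
    contrast = neg$contrast + effect * (pos$contrast - neg$contrast),
    correlation_length = neg$correlation_length +
      effect * (pos$correlation_length - neg$correlation_length),
    noise_sd = neg$noise_sd + effect * (pos$noise_sd - neg$noise_sd))
}

# Deterministic per-subject child seed: integer mixing of the master
# seed with the subject index, kept inside the 32-bit signed range.
.child_seed <- function(seed, index) {
  (as.double(seed) * 1009 + as.double(index) * 9973) %% 2147483647
}

# Separable Gaussian smoothing with symmetric boundary extension.
.gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- min(max(1L, ceiling(3 * sigma)), nrow(m) - 1L)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  smooth1 <- function(x) {
    ext <- c(x[r:1], x, x[length(x):(length(x) - r + 1L)])
    stats::filter(ext, k, sides = 2)[(r + 1L):(r + length(x))]
  }
  m2 <- apply(m, 2L, smooth1)
  t(apply(t(m2), 2L, smooth1))
}

#' Generate one synthetic tumor-like grayscale ROI image
#'
#' A smooth Gaussian random field (white noise smoothed at
#' `correlation_length`, rescaled to `contrast`) is added to the base
#' intensity together with pixelwise white noise, multiplied by a soft
#' elliptical tumor support, clipped to `[0, 255]` and quantised to
#' 8 bits.  Fully deterministic given `(params, size, seed)`; the
#' caller's RNG state is left untouched.  The soft support thresholded
#' at one half becomes the image's ROI mask, and the fraction of pixels
#' clipped during quantisation is attached as attribute
#' `"clip_fraction"`.
#'
#' @param params A [class_texture_params()].
#' @param size Image side in pixels (at least 16).
#' @param seed Integer seed.
#' @param subject_id Optional identifier.
#' @return A [gray_image()] with mask.
#' @export
generate_image <- function(params, size = 64L, seed = 1L,
                           subject_id = NULL) {
  stopifnot(inherits(params, "class_texture_params"), size >= 16L)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  field <- matrix(stats::rnorm(size * size), size, size)
  if (params$contrast > 0) {
    field <- .gauss_smooth(field, params$correlation_length)
    field <- field / stats::sd(field) * params$contrast
  } else {
    field <- field * 0
  }
  img <- params$base_intensity + field +
    matrix(stats::rnorm(size * size, sd = params$noise_sd), size, size)
  # soft elliptical support: normalized elliptical radius with a
  # sigmoid falloff at the boundary
  cx <- (size + 1) / 2
  xs <- (seq_len(size) - cx) / (0.44 * size)
  ys <- (seq_len(size) - cx) / (0.38 * size)
  r <- sqrt(outer(xs^2, ys^2, `+`))
  w <- 1 / (1 + exp((r - 1) / 0.05))
  img <- img * w
  clipped <- mean(img < -0.5 | img > 255.49)
  px <- round(pmin(pmax(img, 0), 255))
  out <- gray_image(px, mask = w >= 0.5, subject_id = subject_id)
  attr(out, "clip_fraction") <- clipped
  out
}

#' Generate a two-class synthetic image cohort
#'
#' Positive-class subjects are drawn at the effect-interpolated texture
#' parameters, negative-class subjects at `params_neg`; every subject
#' gets an independent child seed derived from `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return List with `images` (list of [gray_image()], positives first)
#'   and `labels` (tibble of `subject_id`, `label`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  p_pos <- .interp_params(config$params_neg, config$params_pos,
                          config$effect)
  n <- config$n_pos + config$n_neg
  ids <- sprintf("s%02d", seq_len(n))
  labels <- c(rep(1L, config$n_pos), rep(0L, config$n_neg))
  images <- purrr::map(seq_len(n), function(i) {
    generate_image(if (labels[i] == 1L) p_pos else config$params_neg,
                   size = config$image_size,
                   seed = .child_seed(config$seed, i),
                   subject_id = ids[i])
  })
  list(images = images,
       labels = tibble::tibble(subject_id = ids, label = labels))
}

#' Generate a feature-level synthetic cohort
#'
#' Bypasses the imaging stage: draws a 120-feature table directly, for
#' unit-testing the screening and discriminant stages.  A designated
#' subset of features receives a positive-class mean shift of
#' `config$effect` within-class standard deviations; all other features
#' are null.  With `rho > 0` the features additionally share an
#' exchangeable within-class correlation through a common subject-level
#' factor; the default `rho = 0` (independent features) is the clean
#' calibration null for screening and selection.
#'
#' @param config A [cohort_config()] (`image_size` is ignored;
#'   `effect` is the shift in SD units).
#' @param informative Names of the shifted features (default: the four
#'   features of [ds_reference_model()]).
#' @param rho Exchangeable within-class correlation in `[0, 1)`.
#' @return Feature table tibble (`subject_id`, `label`, 120 features).
#' @export
generate_feature_cohort <- function(config,
                                    informative = c(
                                      "db2dec2sd", "bior33dec1max",
                                      "bior33dec3mn", "sym5dec2mn"),
                                    rho = 0) {
  stopifnot(inherits(config, "synthetic_cohort_config"),
            rho >= 0, rho < 1)
  feats <- feature_names()
  stopifnot(all(informative %in% feats))
  n <- config$n_pos + config$n_neg
  labels <- c(rep(1L, config$n_pos), rep(0L, config$n_neg))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  u <- stats::rnorm(n)  # subject-level shared factor
  X <- sqrt(rho) * matrix(u, n, length(feats)) +
    sqrt(1 - rho) * matrix(stats::rnorm(n * length(feats)), n,
                           length(feats))
  colnames(X) <- feats
  X[labels == 1L, informative] <- X[labels == 1L, informative] +
    config$effect
  out <- tibble::as_tibble(X)
  tibble::add_column(out,
                     subject_id = sprintf("s%02d", seq_len(n)),
                     label = labels, .before = 1L)
}

#' Write a synthetic cohort to disk
#'
#' Saves every image as PNG (or BMP) plus a `labels.csv` with columns
#' `subject_id,label,path`, so the file-based pipeline can be driven
#' end-to-end exactly as with real exported images.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param format `"png"` or `"bmp"`.
#' @return Path of the labels CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("png", "bmp")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(cohort$images, function(im) {
    p <- file.path(dir, paste0(im$subject_id, ".", format))
    write_gray_image(im, p)
    p
  }, character(1))
  labels <- tibble::add_column(cohort$labels, path = paths)
  csv <- file.path(dir, "labels.csv")
  readr::write_csv(labels, csv)
  invisible(csv)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param labels_csv Path to the labels CSV
#'   (`subject_id,label,path`).
#' @return List with `images` and `labels` as in [generate_cohort()].
#' @export
read_cohort <- function(labels_csv) {
  labels <- tibble::as_tibble(utils::read.csv(labels_csv,
                                              stringsAsFactors = FALSE))
  labels$label <- as.integer(labels$label)
  labels$subject_id <- as.character(labels$subject_id)
  base <- dirname(labels_csv)
  images <- purrr::map2(labels$path, labels$subject_id, function(p, id) {
    if (!file.exists(p)) p <- file.path(base, basename(p))
    read_gray_image(p, subject_id = id)
  })
  list(images = images, labels = labels[c("subject_id", "label")])
}
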