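#' Supported mother wavelets
#'
#' The ten mother wavelets used for texture feature extraction, in their
#' canonical (flattened) spelling: Haar/Daubechies `db1`, `db2`, `db4`,
#' Coiflets `coif1`, `coif5`, biorthogonal splines `bior22`, `bior33`
#' (i.e. bior2.2 / bior3.3), and Symlets `sym2`, `sym3`, `sym5`.
#'
#' @return Character vector of the ten canonical wavelet identifiers.
#' @export
#' @examples
#' wavetex_wavelets()
wavetex_wavelets <- function() {
  c("db1", "db2", "db4", "coif1", "coif5",
    "bior22", "bior33", "sym2", "sym3", "sym5")
}

# Canonicalise a wavelet identifier: dotted biorthogonal names are
# flattened ("bior2.2" -> "bior22") and the legacy "sim*" spelling is
# accepted as an alias for the Symlets ("sim5" -> "sym5").
.canonical_wavelet <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  key <- gsub(".", "", tolower(name), fixed = TRUE)
  key <- sub("^sim", "sym", key)
  key
}

#' Retrieve the analysis/synthesis filter bank of a named wavelet
#'
#' Returns the decomposition (analysis) and reconstruction (synthesis)
#' filter taps of one of the ten supported mother wavelets, as
#' double-precision values from the standard published tables.  Dotted
#' spellings (`"bior2.2"`) and the `"sim*"` alias for the Symlets are
#' accepted.
#'
#' All banks satisfy `sum(dec_lo) == sqrt(2)` and `sum(dec_hi) == 0`
#' (to 1e-10); for the orthogonal families (db/coif/sym) the
#' reconstruction filters are the time-reversed decomposition filters,
#' while the biorthogonal splines carry a distinct dual bank.
#'
#' @param name Wavelet identifier, one of [wavetex_wavelets()] or an
#'   accepted alias.
#' @return An object of class `wtx_filter_bank`: a list with elements
#'   `name`, `orthogonal`, and the four tap vectors `dec_lo`, `dec_hi`,
#'   `rec_lo`, `rec_hi`.
#' @export
#' @examples
#' fb <- filter_bank("db1")
#' fb$dec_lo  # c(1, 1) / sqrt(2)
filter_bank <- function(name) {
  key <- .canonical_wavelet(name)
  fb <- .wavelet_filters[[key]]
  if (is.null(fb)) {
    stop("unknown wavelet identifier '", name, "'; supported: ",
         paste(wavetex_wavelets(), collapse = ", "), call. = FALSE)
  }
  structure(fb, class = "wtx_filter_bank")
}

.as_filter_bank <- function(fb) {
  if (inherits(fb, "wtx_filter_bank")) fb else filter_bank(fb)
}

# --- 1D building blocks -----------------------------------------------------
#
# Convention (fixed by bit-level agreement with the reference DWT
# implementation, symmetric mode): extend the signal by flen-1 samples on
# each side with half-point symmetric reflection, run a full linear
# convolution with the filter, and keep samples flen, flen+2, ... (0-based),
# giving floor((n + flen - 1)/2) coefficients.

.symmetric_extend <- function(x, k) {
  if (k == 0L) return(x)
  n <- length(x)
  # half-point reflection repeats the edge sample ([x2 x1 | x1 x2 ...])
  # and keeps bouncing when the extension outruns the signal, so
  # filters longer than the signal are handled like the reference
  # implementation
  j <- (-k):(n + k - 1L)          # 0-based positions of the extension
  m <- j %% (2L * n)
  idx <- ifelse(m < n, m, 2L * n - 1L - m)
  x[idx + 1L]
}

.conv_full <- function(x, f) {
  nx <- length(x)
  nf <- length(f)
  y <- numeric(nx + nf - 1L)
  for (j in seq_len(nf)) {
    y[j:(j + nx - 1L)] <- y[j:(j + nx - 1L)] + f[j] * x
  }
  y
}

.dwt1 <- function(x, filt) {
  fl <- length(filt)
  n <- length(x)
  ext <- if (fl > 1L) .symmetric_extend(x, fl - 1L) else x
  y <- .conv_full(ext, filt)
  outlen <- (n + fl - 1L) %/% 2L
  y[seq.int(fl + 1L, by = 2L, length.out = outlen)]
}

.idwt1 <- function(ca, cd, rec_lo, rec_hi, target_len) {
  fl <- length(rec_lo)
  up <- function(c) {
    u <- numeric(2L * length(c))
    u[seq.int(1L, by = 2L, length.out = length(c))] <- c
    u
  }
  y <- .conv_full(up(ca), rec_lo) + .conv_full(up(cd), rec_hi)
  outlen <- 2L * length(ca) - fl + 2L
  start <- fl - 1L  # 1-based
  if (start < 1L) start <- 1L
  rec <- y[start:(start + outlen - 1L)]
  rec[seq_len(target_len)]
}

# Filter every row (resp. column) of a matrix and downsample.
.dwt_rows <- function(m, filt) {
  out <- apply(m, 1L, .dwt1, filt = filt)   # apply() transposes
  matrix(out, nrow = nrow(m), byrow = TRUE)
}
.dwt_cols <- function(m, filt) {
  out <- apply(m, 2L, .dwt1, filt = filt)
  matrix(out, ncol = ncol(m))
}
.idwt_cols <- function(ca, cd, lo, hi, target_rows) {
  out <- vapply(seq_len(ncol(ca)), function(j) {
    .idwt1(ca[, j], cd[, j], lo, hi, target_rows)
  }, numeric(target_rows))
  matrix(out, nrow = target_rows)
}
.idwt_rows <- function(ca, cd, lo, hi, target_cols) {
  out <- vapply(seq_len(nrow(ca)), function(i) {
    .idwt1(ca[i, ], cd[i, ], lo, hi, target_cols)
  }, numeric(target_cols))
  matrix(out, nrow = nrow(ca), byrow = TRUE)
}

#' Single-level 2D discrete wavelet transform
#'
#' Decomposes a coefficient matrix into one approximation and three
#' detail subbands by separable row/column filtering with symmetric
#' (half-point) boundary extension and dyadic downsampling.  The
#' convention is tied to the reference filter-bank implementation:
#' each output dimension is `floor((n + taps - 1) / 2)`.
#'
#' @param image Numeric matrix of finite values, at least 2 in each
#'   dimension and no smaller than the filter length.
#' @param fb A [filter_bank()] object or wavelet identifier.
#' @param level Dyadic level index stored on the result (bookkeeping
#'   only; the transform itself is identical at every level).
#' @return An object of class `wtx_subbands`: list with `level`, the
#'   subband matrices `cA` (approximation), `cH`, `cV`, `cD`
#'   (horizontal/vertical/diagonal detail, all of identical dimension),
#'   and `input_dim`, the dimension of the decomposed matrix.
#' @export
#' @examples
#' sb <- dwt2_single_level(matrix(5, 8, 8), "db1")
#' unique(as.vector(sb$cA))  # 10: DC gain 2 in 2D
dwt2_single_level <- function(image, fb, level = 1L) {
  fb <- .as_filter_bank(fb)
  image <- as.matrix(image)
  if (any(dim(image) < 2L)) {
    stop("degenerate input: both image dimensions must be >= 2, got ",
         paste(dim(image), collapse = "x"), call. = FALSE)
  }
  if (!all(is.finite(image))) {
    stop("image contains non-finite values", call. = FALSE)
  }
  lo <- .dwt_rows(image, fb$dec_lo)
  hi <- .dwt_rows(image, fb$dec_hi)
  structure(list(
    level = as.integer(level),
    cA = .dwt_cols(lo, fb$dec_lo),
    cH = .dwt_cols(lo, fb$dec_hi),
    cV = .dwt_cols(hi, fb$dec_lo),
    cD = .dwt_cols(hi, fb$dec_hi),
    input_dim = dim(image)
  ), class = "wtx_subbands")
}

#' Maximum feasible decomposition level for an image size
#'
#' @param dim Integer vector of length 2 (image dimensions).
#' @param fb Filter bank or wavelet identifier.
#' @return Largest level count such that every level's input is at
#'   least 2x2 (for filters longer than the signal the symmetric
#'   extension keeps the subbands from shrinking, so the count is
#'   capped at the dyadic depth of the image).
#' @export
max_wavedec_level <- function(dim, fb) {
  fb <- .as_filter_bank(fb)
  fl <- length(fb$dec_lo)
  d <- as.integer(dim)
  cap <- max(1L, floor(log2(min(d))))
  lev <- 0L
  while (all(d >= 2L) && lev < cap) {
    d <- (d + fl - 1L) %/% 2L
    lev <- lev + 1L
  }
  lev
}

#' Multilevel 2D wavelet decomposition pyramid
#'
#' Applies [dwt2_single_level()] recursively: level `k + 1` decomposes
#' level `k`'s approximation subband.  All levels' subband sets are
#' retained, which is what the texture-feature stage consumes.
#'
#' @inheritParams dwt2_single_level
#' @param levels Number of dyadic levels (>= 1).
#' @return Object of class `wtx_pyramid`: list with `wavelet` (canonical
#'   name) and `levels`, a list of `wtx_subbands` for levels `1..L`.
#' @seealso [waverec2()] for the inverse, [extract_features()] for the
#'   feature summaries.
#' @export
wavedec2 <- function(image, fb, levels = 3L) {
  fb <- .as_filter_bank(fb)
  image <- as.matrix(image)
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1", call. = FALSE)
  lmax <- max_wavedec_level(dim(image), fb)
  if (levels > lmax) {
    stop("cannot decompose a ", paste(dim(image), collapse = "x"),
         " image to level ", levels, " with '", fb$name,
         "'; maximum feasible level is ", lmax, call. = FALSE)
  }
  out <- vector("list", levels)
  cur <- image
  for (k in seq_len(levels)) {
    out[[k]] <- dwt2_single_level(cur, fb, level = k)
    cur <- out[[k]]$cA
  }
  structure(list(wavelet = fb$name, levels = out), class = "wtx_pyramid")
}

#' Inverse multilevel 2D wavelet transform
#'
#' Reconstructs the original matrix from a [wavedec2()] pyramid.  Used
#' for verifying perfect reconstruction; the analysis pipeline itself
#' only consumes forward coefficients.
#'
#' @param pyramid A `wtx_pyramid` from [wavedec2()].
#' @param fb Filter bank or wavelet identifier; must match the wavelet
#'   the pyramid was built with.
#' @return Numeric matrix with the dimensions of the decomposed image;
#'   equal to it within 1e-8 in max absolute error.
#' @export
waverec2 <- function(pyramid, fb) {
  fb <- .as_filter_bank(fb)
  if (!inherits(pyramid, "wtx_pyramid")) {
    stop("pyramid must be a wavedec2() result", call. = FALSE)
  }
  if (!identical(pyramid$wavelet, fb$name)) {
    stop("pyramid was built with wavelet '", pyramid$wavelet,
         "' but reconstruction was requested with '", fb$name, "'",
         call. = FALSE)
  }
  lo <- fb$rec_lo
  hi <- fb$rec_hi
  cur <- pyramid$levels[[length(pyramid$levels)]]$cA
  for (k in rev(seq_along(pyramid$levels))) {
    sb <- pyramid$levels[[k]]
    d <- sb$input_dim
    l_rec <- .idwt_cols(cur, sb$cH, lo, hi, d[1L])
    h_rec <- .idwt_cols(sb$cV, sb$cD, lo, hi, d[1L])
    cur <- .idwt_rows(l_rec, h_rec, lo, hi, d[2L])
  }
  cur
}
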