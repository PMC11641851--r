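#' Grayscale ROI image
#'
#' The analysis unit: a rectangular 8-bit grayscale pixel matrix with an
#' optional binary region-of-interest mask of the same shape.
#'
#' @param pixels Integer-valued matrix with intensities in `[0, 255]`.
#' @param mask Optional logical (or 0/1) matrix of identical shape
#'   marking the ROI; must contain at least one `TRUE` pixel.
#' @param subject_id Optional opaque identifier carried through the
#'   pipeline.
#' @return Object of class `gray_image` (list with `pixels`, `mask`,
#'   `subject_id`).
#' @export
gray_image <- function(pixels, mask = NULL, subject_id = NULL) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || !all(is.finite(pixels))) {
    stop("pixels must be a finite numeric matrix", call. = FALSE)
  }
  if (any(pixels < 0 | pixels > 255) || any(pixels != round(pixels))) {
    stop("pixels must be integers in [0, 255]", call. = FALSE)
  }
  storage.mode(pixels) <- "double"
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    if (!identical(dim(mask), dim(pixels))) {
      stop("mask dimensions must match pixel dimensions", call. = FALSE)
    }
    mask <- mask != 0
    if (!any(mask)) stop("mask has no ROI pixels", call. = FALSE)
  }
  structure(list(pixels = pixels, mask = mask,
                 subject_id = subject_id), class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat("<gray_image ", nrow(x$pixels), "x", ncol(x$pixels),
      if (!is.null(x$mask)) paste0(", masked (", sum(x$mask), " px)"),
      if (!is.null(x$subject_id)) paste0(", subject ", x$subject_id),
      ">\n", sep = "")
  invisible(x)
}

#' Crop an image to the bounding box of its ROI mask
#'
#' The tight bounding-box rectangle of the mask is what enters the
#' wavelet decomposition; the irregular mask is not applied to the
#' coefficients (they have no one-to-one pixel mapping).  Images without
#' a mask are treated as already cropped and returned unchanged.
#'
#' @param image A [gray_image()].
#' @param min_size Minimum allowed crop dimension (default 8); smaller
#'   ROIs cannot support a three-level decomposition and are rejected.
#' @return A `gray_image` restricted to the bounding box, with the mask
#'   cropped alongside.
#' @export
crop_to_roi <- function(image, min_size = 8L) {
  stopifnot(inherits(image, "gray_image"))
  if (is.null(image$mask)) return(image)
  rows <- range(which(rowSums(image$mask) > 0))
  cols <- range(which(colSums(image$mask) > 0))
  px <- image$pixels[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  if (any(dim(px) < min_size)) {
    stop("ROI bounding box ", paste(dim(px), collapse = "x"),
         " is smaller than the minimum ", min_size, "x", min_size,
         call. = FALSE)
  }
  gray_image(px,
             mask = image$mask[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE],
             subject_id = image$subject_id)
}

# --- disk formats -----------------------------------------------------------

.luminosity <- function(arr) {
  # classic luma weights for RGB -> gray conversion
  0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
}

#' Read a grayscale image from PNG or BMP
#'
#' 8-bit single-channel input is expected; multi-channel images are
#' converted to gray by luminosity with a warning.  BMP support covers
#' uncompressed 8-bit palette and 24-bit files (the export format of the
#' imaging workstation workflow this pipeline mirrors).
#'
#' @param path File path ending in `.png` or `.bmp`.
#' @param mask_path Optional path to a same-sized image whose nonzero
#'   pixels mark the ROI.
#' @param subject_id Optional identifier; defaults to the file stem.
#' @return A [gray_image()].
#' @export
read_gray_image <- function(path, mask_path = NULL, subject_id = NULL) {
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  px <- .read_gray_pixels(path)
  mask <- if (!is.null(mask_path)) .read_gray_pixels(mask_path) != 0
  gray_image(px, mask = mask, subject_id = subject_id)
}

.read_gray_pixels <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "png") {
    arr <- png::readPNG(path)
    if (length(dim(arr)) == 3L) {
      warning("multi-channel image '", basename(path),
              "' converted to gray by luminosity", call. = FALSE)
      arr <- .luminosity(arr)
    }
    round(arr * 255)
  } else if (ext == "bmp") {
    .read_bmp_gray(path)
  } else {
    stop("unsupported image format '.", ext, "' (use PNG or BMP)",
         call. = FALSE)
  }
}

#' Write a grayscale image to PNG or BMP
#'
#' @param image A [gray_image()].
#' @param path Output path; the extension selects the format.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path) {
  stopifnot(inherits(image, "gray_image"))
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "png") {
    png::writePNG(image$pixels / 255, path)
  } else if (ext == "bmp") {
    .write_bmp_gray(image$pixels, path)
  } else {
    stop("unsupported image format '.", ext, "' (use PNG or BMP)",
         call. = FALSE)
  }
  invisible(path)
}

# Minimal uncompressed BMP support (no installed package reads BMP).
# 8-bit files use a palette lookup; 24-bit files are converted by
# luminosity with a warning.  Rows are stored bottom-up, 4-byte aligned.

.read_u <- function(con, n, size) {
  readBin(con, "integer", n = n, size = size, signed = size > 2,
          endian = "little")
}

.read_bmp_gray <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2, useBytes = TRUE)
  if (!identical(magic, "BM")) stop("not a BMP file: ", path, call. = FALSE)
  invisible(.read_u(con, 2, 4))          # file size, reserved
  data_offset <- .read_u(con, 1, 4)
  header_size <- .read_u(con, 1, 4)
  if (header_size < 40) stop("unsupported BMP header", call. = FALSE)
  width <- .read_u(con, 1, 4)
  height <- .read_u(con, 1, 4)
  invisible(.read_u(con, 1, 2))          # planes
  bpp <- .read_u(con, 1, 2)
  compression <- .read_u(con, 1, 4)
  if (compression != 0) stop("compressed BMP not supported", call. = FALSE)
  if (!bpp %in% c(8L, 24L)) {
    stop("only 8-bit and 24-bit uncompressed BMP supported, got ",
         bpp, "-bit", call. = FALSE)
  }
  palette <- NULL
  if (bpp == 8L) {
    seek(con, 14L + header_size)         # palette starts after the DIB
    n_pal <- (data_offset - 14L - header_size) %/% 4L
    pal_raw <- readBin(con, "raw", n = n_pal * 4L)
    pal <- matrix(as.integer(pal_raw), ncol = 4L, byrow = TRUE)  # B G R A
    palette <- 0.299 * pal[, 3] + 0.587 * pal[, 2] + 0.114 * pal[, 1]
  }
  seek(con, data_offset)
  bytes_per_px <- bpp %/% 8L
  row_bytes <- ((width * bytes_per_px + 3L) %/% 4L) * 4L
  raw_px <- readBin(con, "raw", n = row_bytes * height)
  m <- matrix(as.integer(raw_px), nrow = row_bytes)[seq_len(width * bytes_per_px), ,
                                                    drop = FALSE]
  if (bpp == 8L) {
    gray <- matrix(palette[m + 1L], nrow = width)
  } else {
    warning("24-bit BMP converted to gray by luminosity", call. = FALSE)
    b <- m[seq(1, nrow(m), 3), , drop = FALSE]
    g <- m[seq(2, nrow(m), 3), , drop = FALSE]
    r <- m[seq(3, nrow(m), 3), , drop = FALSE]
    gray <- 0.299 * r + 0.587 * g + 0.114 * b
  }
  # columns of `gray` are bottom-up image rows
  round(t(gray)[height:1, , drop = FALSE])
}

.write_bmp_gray <- function(pixels, path) {
  h <- nrow(pixels)
  w <- ncol(pixels)
  row_bytes <- ((w + 3L) %/% 4L) * 4L
  data_offset <- 14L + 40L + 256L * 4L
  file_size <- data_offset + row_bytes * h
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("BM", con, eos = NULL, useBytes = TRUE)
  writeBin(as.integer(c(file_size, 0L, data_offset)), con, size = 4,
           endian = "little")
  writeBin(as.integer(c(40L, w, h)), con, size = 4, endian = "little")
  writeBin(as.integer(c(1L, 8L)), con, size = 2, endian = "little")
  writeBin(as.integer(c(0L, row_bytes * h, 2835L, 2835L, 256L, 0L)), con,
           size = 4, endian = "little")
  pal <- as.vector(rbind(0:255, 0:255, 0:255, 0L))  # B G R A per entry
  writeBin(as.raw(pal), con)
  padded <- matrix(0L, nrow = row_bytes, ncol = h)
  padded[seq_len(w), ] <- t(pixels[h:1, , drop = FALSE])
  writeBin(as.raw(padded), con)
  invisible(path)
}
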