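#' Grayscale plate image
#'
#' Container for a rectangular grayscale pixel grid as produced by a plate
#' imager. Pixels are stored as a numeric matrix in `(row, col)` orientation
#' with a 1-based, top-left origin. The `polarity` flag records whether high
#' values mean more light (`"raw"`, the camera convention, where dense
#' invasive scars are dark) or more invasion signal (`"inverted"`, the
#' convention all quantification runs in).
#'
#' @param pixels Numeric matrix of nonnegative intensities.
#' @param bit_depth Integer, 8 or 16; values must lie in `[0, 2^bit_depth - 1]`.
#' @param polarity `"raw"` or `"inverted"`.
#'
#' @return An `intensity_image`: the pixel matrix with class and metadata
#'   attributes.
#' @examples
#' img <- intensity_image(matrix(0:99, 10, 10), bit_depth = 8)
#' dim(img)
#' @export
intensity_image <- function(pixels, bit_depth = 8, polarity = c("raw", "inverted")) {
  polarity <- match.arg(polarity)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("`pixels` must be a numeric matrix (rectangular grid).")
  }
  if (nrow(pixels) < 1 || ncol(pixels) < 1) {
    abort("image must be at least 1x1")
  }
  if (anyNA(pixels) || any(!is.finite(pixels))) {
    abort("image contains missing or non-finite intensities")
  }
  if (!bit_depth %in% c(8L, 16L)) abort("`bit_depth` must be 8 or 16")
  maxval <- 2^bit_depth - 1
  if (any(pixels < 0) || any(pixels > maxval)) {
    abort(sprintf("intensities must lie in [0, %d] for bit depth %d", maxval, bit_depth))
  }
  structure(pixels,
    bit_depth = as.integer(bit_depth), polarity = polarity,
    class = c("intensity_image", "matrix", "array")
  )
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf(
    "<intensity_image> %d x %d, %d-bit, polarity: %s, range [%g, %g]\n",
    nrow(x), ncol(x), attr(x, "bit_depth"), attr(x, "polarity"),
    min(x), max(x)
  ))
  invisible(x)
}

img_maxval <- function(img) 2^attr(img, "bit_depth") - 1

img_polarity <- function(img) attr(img, "polarity") %||% "raw"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a grayscale plate image from TIFF or PNG
#'
#' Multi-channel images are averaged to a single grayscale channel. PNG input
#' (decoded to `[0, 1]` by libpng) is rescaled to the stated bit depth; TIFF
#' input is read with its native integer values when possible.
#'
#' @param path File path ending in `.tif`, `.tiff` or `.png`.
#' @param bit_depth Bit depth to record (and to rescale PNG input to).
#' @param polarity Polarity flag to record for the image (see
#'   [intensity_image()]).
#' @return An [intensity_image()].
#' @export
read_plate_image <- function(path, bit_depth = 8, polarity = c("raw", "inverted")) {
  polarity <- match.arg(polarity)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    px <- png::readPNG(path) * (2^bit_depth - 1)
  } else {
    abort(sprintf("unsupported image format: '%s' (use TIFF or PNG)", ext))
  }
  if (length(dim(px)) == 3) px <- apply(px, c(1, 2), mean)
  intensity_image(round(px), bit_depth = bit_depth, polarity = polarity)
}

#' Write a plate image to TIFF or PNG
#'
#' @param img An [intensity_image()].
#' @param path Output path ending in `.tif`, `.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_plate_image <- function(img, path) {
  scaled <- unclass(img) / img_maxval(img)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(scaled, path, bits.per.sample = attr(img, "bit_depth"))
  } else if (ext == "png") {
    png::writePNG(scaled, path)
  } else {
    abort(sprintf("unsupported image format: '%s' (use TIFF or PNG)", ext))
  }
  invisible(path)
}

# Closed-disk membership on the pixel grid: a pixel belongs to the disk when
# its center lies within `radius` of `center` (row, col), 1-based.
disk_mask <- function(nrow, ncol, center, radius) {
  dr <- matrix(seq_len(nrow) - center[[1]], nrow, ncol)
  dc <- matrix(rep(seq_len(ncol) - center[[2]], each = nrow), nrow, ncol)
  dr * dr + dc * dc <= radius * radius + 1e-9
}
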