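#' Background-subtract, invert and contrast-rescale a scar image
#'
#' Prepares a washed-plate image for invasion quantification. The local
#' background is estimated by a rolling-ball style morphological opening with
#' a disc structuring element of the stated radius and subtracted, leaving
#' only scar-scale signal; the result is then rescaled so that the stated low
#' and high percentiles of the background-free intensities map to 0 and the
#' bit-depth maximum. The output polarity is always `"inverted"` (higher
#' value = more invasion signal).
#'
#' Imagers differ in whether dense invasive cells photograph bright or dark.
#' `signal = "bright"` (default) assumes scars are brighter than the plate;
#' `signal = "dark"` flips the image (`max - value`) before background
#' estimation, which is the right choice for transmitted-light images where
#' scars are dark. Every image of a batch must be treated with identical
#' parameters; use [preprocess_scar_batch()] to enforce this.
#'
#' @param raw An [intensity_image()] with polarity `"raw"`.
#' @param background_radius Disc radius (pixels) of the structuring element;
#'   must be positive and smaller than the smallest image dimension.
#'   Default 50, a typical scar-scale radius for plate images.
#' @param contrast_percentiles Length-2 numeric `(low, high)` in `[0, 100]`,
#'   `low < high`. Defaults to the 1st and 99th percentiles.
#' @param signal Whether invasion signal is `"bright"` or `"dark"` in `raw`.
#' @return An [intensity_image()] with polarity `"inverted"`, carrying the
#'   parameters used as attributes (`background_radius`,
#'   `contrast_percentiles`) for the run log.
#' @examples
#' raw <- intensity_image(matrix(10, 32, 32) + diag(32) * 0)
#' out <- preprocess_scar_image(raw, background_radius = 5)
#' all(out == 0) # constant field has no foreground
#' @export
preprocess_scar_image <- function(raw, background_radius = 50,
                                  contrast_percentiles = c(1, 99),
                                  signal = c("bright", "dark")) {
  signal <- match.arg(signal)
  if (!inherits(raw, "intensity_image")) raw <- intensity_image(raw)
  if (img_polarity(raw) != "raw") {
    abort("`raw` has already been inverted; preprocess operates on raw-polarity images")
  }
  if (background_radius <= 0) abort("`background_radius` must be positive")
  if (2 * background_radius + 1 > min(dim(raw))) {
    abort("`background_radius` is larger than the smallest image dimension allows")
  }
  check_percentiles(contrast_percentiles)

  maxval <- img_maxval(raw)
  px <- unclass(raw)
  if (signal == "dark") px <- maxval - px
  bg <- morph_open(px, background_radius, maxval)
  tophat <- pmax(px - bg, 0)
  out <- contrast_rescale(tophat, contrast_percentiles, maxval)
  out <- intensity_image(out, bit_depth = attr(raw, "bit_depth"), polarity = "inverted")
  attr(out, "background_radius") <- background_radius
  attr(out, "contrast_percentiles") <- contrast_percentiles
  out
}

#' Preprocess a batch of scar images with one shared parameter set
#'
#' Applies the same background subtraction to every image and then rescales
#' all of them with a single linear contrast map computed from the pooled
#' percentiles of the whole batch. This mirrors the equal-treatment rule
#' that all images of an experiment must receive the same adjustments, and
#' -- unlike rescaling each image by its own percentiles -- preserves the
#' intensity ratios between images that relative invasion depends on.
#'
#' @param images A (optionally named) list of raw [intensity_image()]s.
#' @inheritParams preprocess_scar_image
#' @return A list of preprocessed images, with a `run_log` attribute
#'   recording the shared parameters.
#' @export
preprocess_scar_batch <- function(images, background_radius = 50,
                                  contrast_percentiles = c(1, 99),
                                  signal = c("bright", "dark")) {
  signal <- match.arg(signal)
  stopifnot(is.list(images), length(images) >= 1)
  check_percentiles(contrast_percentiles)
  tophats <- lapply(images, function(img) {
    if (!inherits(img, "intensity_image")) img <- intensity_image(img)
    if (img_polarity(img) != "raw") abort("batch images must have raw polarity")
    if (2 * background_radius + 1 > min(dim(img))) {
      abort("`background_radius` is larger than the smallest image dimension allows")
    }
    maxval <- img_maxval(img)
    px <- unclass(img)
    if (signal == "dark") px <- maxval - px
    pmax(px - morph_open(px, background_radius, maxval), 0)
  })
  maxval <- img_maxval(
    if (inherits(images[[1]], "intensity_image")) images[[1]] else intensity_image(images[[1]])
  )
  pooled <- unlist(lapply(tophats, as.vector))
  qs <- quantile(pooled, probs = contrast_percentiles / 100, names = FALSE)
  out <- lapply(seq_along(images), function(i) {
    px <- if (qs[2] <= qs[1]) {
      matrix(0, nrow(tophats[[i]]), ncol(tophats[[i]]))
    } else {
      pmin(pmax((tophats[[i]] - qs[1]) / (qs[2] - qs[1]), 0), 1) * maxval
    }
    img <- intensity_image(px,
      bit_depth = attr(
        if (inherits(images[[i]], "intensity_image")) images[[i]] else intensity_image(images[[i]]),
        "bit_depth"
      ),
      polarity = "inverted"
    )
    attr(img, "background_radius") <- background_radius
    attr(img, "contrast_percentiles") <- contrast_percentiles
    img
  })
  names(out) <- names(images)
  attr(out, "run_log") <- list(
    background_radius = background_radius,
    contrast_percentiles = contrast_percentiles,
    contrast_bounds = qs,
    signal = signal, n_images = length(images)
  )
  out
}

check_percentiles <- function(p) {
  if (length(p) != 2 || anyNA(p) || p[1] < 0 || p[2] > 100 || p[1] >= p[2]) {
    abort("`contrast_percentiles` must be (low, high) with 0 <= low < high <= 100")
  }
  invisible(p)
}

# Grayscale morphological opening with a disc element. EBImage operates on
# [0, 1] intensities, so scale through the bit-depth maximum.
morph_open <- function(px, radius, maxval) {
  kern <- EBImage::makeBrush(2 * as.integer(radius) + 1, shape = "disc")
  as.matrix(EBImage::opening(px / maxval, kern)) * maxval
}

# Map the (low, high) percentiles of `px` to [0, maxval], clamping outside.
# A constant field (high == low) carries no foreground and maps to zero.
contrast_rescale <- function(px, percentiles, maxval) {
  qs <- quantile(px, probs = percentiles / 100, names = FALSE)
  if (qs[2] <= qs[1]) {
    return(matrix(0, nrow(px), ncol(px)))
  }
  pmin(pmax((px - qs[1]) / (qs[2] - qs[1]), 0), 1) * maxval
}
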