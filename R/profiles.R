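#' Crop a square window around an invasive scar
#'
#' Cuts a `size` x `size` window centered on the scar center, the first step
#' of plot-profile analysis. Typical sizes track the scar footprint per
#' medium (for example 200-300 px). When the window extends past the image
#' the crop is zero-padded to the exact requested size, with a warning.
#'
#' @param image An [intensity_image()].
#' @param center `(row, col)` scar center, 1-based.
#' @param size Window side length in pixels; must be even and at least
#'   `band_height`.
#' @param band_height Band height the crop must accommodate (default 40).
#' @return An [intensity_image()] of dimensions `size` x `size` with the
#'   polarity of the input.
#' @export
crop_scar <- function(image, center, size = 200, band_height = 40) {
  if (!inherits(image, "intensity_image")) image <- intensity_image(image)
  if (size %% 2 != 0) abort("`size` must be even")
  if (size < band_height) abort("`size` must be at least the band height")
  rows <- (center[1] - size / 2 + 1):(center[1] + size / 2)
  cols <- (center[2] - size / 2 + 1):(center[2] + size / 2)
  out <- matrix(0, size, size)
  rok <- rows >= 1 & rows <= nrow(image)
  cok <- cols >= 1 & cols <= ncol(image)
  if (!all(rok) || !all(cok)) {
    warn("crop window extends past the image; zero-padding to requested size")
  }
  out[rok, cok] <- unclass(image)[rows[rok], cols[cok]]
  intensity_image(out, bit_depth = attr(image, "bit_depth"), polarity = img_polarity(image))
}

#' Extract a plot profile across a scar crop
#'
#' Draws a band of height `band_height` across the midsection of the crop,
#' edge to edge, along the axis at `axis_angle`, and returns the mean grey
#' value of each band column -- the transect used to read microenvironment
#' invasion patterns. The polarity of the input is recorded, never flipped:
#' on raw-polarity images less invasion (light pixels) gives high values;
#' on inverted images more invasion gives high values.
#'
#' Axis-aligned angles (multiples of 90 degrees) are computed exactly as
#' per-column (or per-row) means; other angles rotate the sampling frame
#' about the crop center with bilinear interpolation (sampling coordinates
#' are clamped to the crop, replicating edge pixels).
#'
#' @param crop A square [intensity_image()] from [crop_scar()].
#' @param axis_angle Transect angle in degrees (0 = horizontal).
#' @param band_height Band height in pixels (default 40).
#' @return A `plot_profile` tibble with columns `position`, `mean_grey` and
#'   attributes `band_height`, `axis_angle`, `polarity`, `crop_size`.
#' @examples
#' crop <- intensity_image(matrix(7, 40, 40))
#' extract_plot_profile(crop, axis_angle = 0)$mean_grey[1] # constant image -> 7
#' @export
extract_plot_profile <- function(crop, axis_angle = 0, band_height = 40) {
  if (!inherits(crop, "intensity_image")) crop <- intensity_image(crop)
  s <- nrow(crop)
  if (s != ncol(crop)) abort("`crop` must be square")
  if (band_height > s) abort("band is taller than the crop")
  px <- unclass(crop)
  ang <- axis_angle %% 180

  if (isTRUE(all.equal(ang, 90))) {
    px <- t(px)
    ang <- 0
  }
  if (isTRUE(all.equal(ang, 0))) {
    r0 <- floor((s - band_height) / 2) + 1
    vals <- colMeans(px[r0:(r0 + band_height - 1), , drop = FALSE])
  } else {
    theta <- ang * pi / 180
    c0 <- (s + 1) / 2
    u <- seq_len(s) - c0
    v <- seq_len(band_height) - (band_height + 1) / 2
    rowpts <- outer(v, u, function(v, u) c0 + u * sin(theta) + v * cos(theta))
    colpts <- outer(v, u, function(v, u) c0 + u * cos(theta) - v * sin(theta))
    vals <- colMeans(matrix(bilinear_sample(px, rowpts, colpts), band_height, s))
  }

  new_plot_profile(vals, band_height, axis_angle, img_polarity(crop), s)
}

new_plot_profile <- function(values, band_height, axis_angle, polarity, crop_size) {
  structure(
    tibble(position = seq_along(values), mean_grey = as.numeric(values)),
    band_height = band_height, axis_angle = axis_angle,
    polarity = polarity, crop_size = crop_size,
    class = c("plot_profile", class(tibble()))
  )
}

# Bilinear interpolation at fractional (row, col) points; coordinates are
# clamped to the image, so sampling replicates edge pixels outside.
bilinear_sample <- function(px, r, c) {
  nr <- nrow(px)
  nc <- ncol(px)
  r <- pmin(pmax(r, 1), nr)
  c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1)
  c0 <- pmin(floor(c), nc - 1)
  fr <- r - r0
  fc <- c - c0
  at <- function(ri, ci) px[cbind(as.vector(ri), as.vector(ci))]
  (1 - fr) * (1 - fc) * at(r0, c0) + (1 - fr) * fc * at(r0, c0 + 1) +
    fr * (1 - fc) * at(r0 + 1, c0) + fr * fc * at(r0 + 1, c0 + 1)
}

#' Average plot profiles taken along several axes
#'
#' Element-wise mean of profiles of equal length and band height, the
#' standard way to report one representative transect from several axes
#' through the same scar.
#'
#' @param profiles List of `plot_profile` objects (see
#'   [extract_plot_profile()]).
#' @return A `plot_profile` with `axis_angle = "composite"`.
#' @export
average_axes_profiles <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 1)
  lens <- vapply(profiles, nrow, integer(1))
  bands <- vapply(profiles, function(p) attr(p, "band_height"), numeric(1))
  if (length(unique(lens)) != 1) abort("profiles differ in length")
  if (length(unique(bands)) != 1) abort("profiles differ in band height")
  vals <- rowMeans(vapply(profiles, function(p) p$mean_grey, numeric(lens[1])))
  new_plot_profile(
    vals, bands[1], "composite",
    attr(profiles[[1]], "polarity"), attr(profiles[[1]], "crop_size")
  )
}

#' Classify the microenvironment invasion pattern of a profile
#'
#' Formalizes the qualitative reading of scar transects: after converting to
#' invasion-positive polarity, the transect is split into a center third and
#' two outer thirds. `center_ratio` is the center-third mean over the
#' overall mean and `ring_ratio` the outer-thirds mean over the overall
#' mean. The call is `center` when the center ratio clears its cut and
#' exceeds the ring ratio, `ring` symmetrically, `uniform` when both ratios
#' sit within `cut - 1` of 1, and `diffuse` otherwise.
#'
#' @param profile A `plot_profile` or numeric vector (length >= 9).
#' @param polarity Polarity of the values; defaults to the profile's
#'   recorded polarity (`"raw"` values are flipped to invasion-positive).
#' @param thresholds Length-2 `(center_cut, ring_cut)`; default 1.25 each.
#' @return A one-row tibble: `label` (one of `uniform`, `center`, `ring`,
#'   `diffuse`), `center_ratio`, `ring_ratio`.
#' @examples
#' classify_invasion_pattern(c(0, 0, 0, 9, 9, 9, 0, 0, 0), polarity = "inverted")
#' @export
classify_invasion_pattern <- function(profile, polarity = NULL,
                                      thresholds = c(1.25, 1.25)) {
  if (inherits(profile, "plot_profile")) {
    if (is.null(polarity)) polarity <- attr(profile, "polarity")
    v <- profile$mean_grey
  } else {
    v <- as.numeric(profile)
  }
  if (is.null(polarity)) polarity <- "inverted"
  n <- length(v)
  if (n < 9) abort("profile too short to split into thirds (need >= 9 positions)")
  stopifnot(length(thresholds) == 2, all(thresholds > 1))
  if (polarity == "raw") v <- max(v) - v

  k <- floor(n / 3)
  center_idx <- (k + 1):(n - k)
  outer_idx <- c(1:k, (n - k + 1):n)
  m <- mean(v)
  if (m == 0) {
    warn("profile has zero overall mean; calling diffuse")
    return(tibble(label = "diffuse", center_ratio = NA_real_, ring_ratio = NA_real_))
  }
  center_ratio <- mean(v[center_idx]) / m
  ring_ratio <- mean(v[outer_idx]) / m
  band <- thresholds - 1

  label <- if (center_ratio >= thresholds[1] && center_ratio > ring_ratio) {
    "center"
  } else if (ring_ratio >= thresholds[2] && ring_ratio > center_ratio) {
    "ring"
  } else if (abs(center_ratio - 1) <= band[1] && abs(ring_ratio - 1) <= band[2]) {
    "uniform"
  } else {
    "diffuse"
  }
  tibble(label = label, center_ratio = center_ratio, ring_ratio = ring_ratio)
}

#' Crop, profile along several axes, and average
#'
#' Convenience wrapper running [crop_scar()], [extract_plot_profile()] for
#' each angle (defaults 0, 60 and 120 degrees through the scar center), and
#' [average_axes_profiles()].
#'
#' @inheritParams crop_scar
#' @param angles Transect angles in degrees.
#' @inheritParams extract_plot_profile
#' @return A composite `plot_profile`.
#' @export
scar_profile <- function(image, center, size = 200, angles = c(0, 60, 120),
                         band_height = 40) {
  crop <- crop_scar(image, center, size, band_height)
  average_axes_profiles(lapply(angles, function(a) {
    extract_plot_profile(crop, axis_angle = a, band_height = band_height)
  }))
}

#' @method autoplot plot_profile
#' @export
autoplot.plot_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$position, .data$mean_grey)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Distance (pixels)", y = "Mean grey value",
      subtitle = sprintf(
        "band height %s px, axis %s, polarity %s",
        attr(object, "band_height"), attr(object, "axis_angle"),
        attr(object, "polarity")
      )
    ) +
    ggplot2::theme_minimal()
}
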