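#' Threshold an image to a binary cell/background mask
#'
#' Pixels strictly on the foreground side of the threshold become `TRUE`.
#' The same threshold must be applied to every image of an assay (the
#' equal-treatment rule); record it per assay rather than auto-thresholding
#' per image.
#'
#' @param image An [intensity_image()] or numeric matrix.
#' @param threshold Intensity threshold within the bit-depth range.
#' @param foreground Which side of the threshold is cells: `"above"`
#'   (default) or `"below"`.
#' @return A `binary_mask`: logical matrix with attributes `threshold_used`
#'   and `polarity_note`.
#' @export
binarize <- function(image, threshold, foreground = c("above", "below")) {
  foreground <- match.arg(foreground)
  if (!inherits(image, "intensity_image")) image <- intensity_image(image)
  maxval <- img_maxval(image)
  if (threshold < 0 || threshold > maxval) {
    abort(sprintf("`threshold` must lie within [0, %d]", maxval))
  }
  px <- unclass(image)
  mask <- if (foreground == "above") px > threshold else px < threshold
  structure(mask,
    threshold_used = threshold,
    polarity_note = sprintf("foreground strictly %s threshold", foreground),
    class = c("binary_mask", "matrix", "array")
  )
}

#' Label connected foreground components
#'
#' Connected-component labeling by iterative minimum-label propagation, at
#' 4- or 8-connectivity. Returns an integer matrix with 0 for background and
#' 1..k for components (labels renumbered in raster order).
#'
#' @param mask Logical matrix (or `binary_mask`).
#' @param connectivity 4 (edge neighbors) or 8 (edge + corner neighbors);
#'   default 8, the Analyze-Particles convention.
#' @return Integer label matrix.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  mask <- mask & !is.na(mask)
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  if (sum(mask) == 0) {
    return(lab)
  }

  shift <- function(m, dr, dc, fill = 0L) {
    out <- matrix(fill, nr, nc)
    rs <- seq_len(nr) - dr
    cs <- seq_len(nc) - dc
    rok <- rs >= 1 & rs <= nr
    cok <- cs >= 1 & cs <= nc
    out[rok, cok] <- m[rs[rok], cs[cok]]
    out
  }
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8) {
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  }
  big <- sum(mask) + 1L
  repeat {
    cur <- ifelse(mask, lab, big)
    nb <- cur
    for (o in offs) {
      nb <- pmin(nb, shift(cur, o[1], o[2], fill = big))
    }
    nb[!mask] <- 0L
    if (all(nb == lab)) break
    lab <- nb
  }
  ids <- unique(lab[lab > 0])
  lab[lab > 0] <- match(lab[lab > 0], sort(ids))
  lab
}

#' Particle statistics of a binary mask
#'
#' Connected-component ("analyze particles") statistics: number of
#' particles, mean particle area and total particle area, after discarding
#' components smaller than `min_size`. Total area is the metric of record
#' for within-colony and plastic adhesion; mean area for liquid-culture cell
#' clusters.
#'
#' @param mask Logical matrix or `binary_mask` (see [binarize()]).
#' @param min_size Minimum particle area in pixels^2 kept (default 4,
#'   suppressing single-pixel noise).
#' @param connectivity Passed to [label_components()].
#' @return A one-row tibble: `n_particles`, `mean_area`, `total_area`,
#'   `min_size_applied`, `empty` (`TRUE` when no particle survives, in which
#'   case `mean_area` is reported as 0).
#' @examples
#' m <- matrix(FALSE, 20, 20); m[5:14, 5:14] <- TRUE
#' particle_stats(m)
#' @export
particle_stats <- function(mask, min_size = 4, connectivity = 8) {
  lab <- label_components(unclass(mask) & TRUE, connectivity)
  sizes <- tabulate(lab[lab > 0])
  sizes <- sizes[sizes >= min_size]
  n <- length(sizes)
  tibble(
    n_particles = n,
    mean_area = if (n > 0) mean(sizes) else 0,
    total_area = sum(sizes),
    min_size_applied = min_size,
    empty = n == 0
  )
}

#' Wild-type-relative adhesion
#'
#' Normalizes per-strain replicate means of a particle metric to the
#' wild-type mean (wild type = 1), with the replicate standard deviation
#' propagated on the normalized scale. Use `metric = "mean_area"` for
#' liquid-culture cluster size and `metric = "total_area"` for
#' within-colony or plastic-well adhesion.
#'
#' @param stats_by_strain Tibble with columns `strain`, `replicate` and the
#'   chosen metric (e.g. one [particle_stats()] row per replicate image).
#' @param wild_type Wild-type strain label.
#' @param metric `"mean_area"` or `"total_area"`.
#' @return Tibble with columns `strain`, `relative_value`, `sd`.
#' @export
relative_adhesion <- function(stats_by_strain, wild_type = "WT",
                              metric = c("mean_area", "total_area")) {
  metric <- match.arg(metric)
  stopifnot(all(c("strain", metric) %in% names(stats_by_strain)))
  per <- stats_by_strain %>%
    group_by(.data$strain) %>%
    summarise(
      m = mean(.data[[metric]]),
      s = if (n() > 1) sd(.data[[metric]]) else NA_real_,
      .groups = "drop"
    )
  if (!wild_type %in% per$strain) abort(sprintf("wild type '%s' absent", wild_type))
  wt <- per$m[per$strain == wild_type]
  if (wt == 0) abort("undefined normalization: wild-type mean is 0")
  per %>%
    mutate(relative_value = .data$m / wt, sd = .data$s / wt) %>%
    select("strain", "relative_value", "sd")
}

#' Particle statistics inside a circular well crop
#'
#' Crops a plastic-well image to the circle of the well (pixels outside set
#' to background), binarizes with the assay threshold, and measures particle
#' statistics; `total_area` is the metric of record for crystal-violet
#' stained adherent cells.
#'
#' @param image An [intensity_image()] of the well.
#' @param well_center `(row, col)` of the well center.
#' @param well_radius Radius in pixels; the circle must fit in the image.
#' @param threshold,foreground Passed to [binarize()].
#' @param min_size,connectivity Passed to [particle_stats()].
#' @return A [particle_stats()] row.
#' @export
well_adhesion <- function(image, well_center, well_radius, threshold,
                          foreground = c("above", "below"),
                          min_size = 4, connectivity = 8) {
  foreground <- match.arg(foreground)
  if (!inherits(image, "intensity_image")) image <- intensity_image(image)
  nr <- nrow(image)
  nc <- ncol(image)
  if (well_center[1] - well_radius < 0.5 || well_center[1] + well_radius > nr + 0.5 ||
    well_center[2] - well_radius < 0.5 || well_center[2] + well_radius > nc + 0.5) {
    abort("well circle lies (partly) outside the image")
  }
  px <- unclass(image)
  bgval <- if (foreground == "above") 0 else img_maxval(image)
  px[!disk_mask(nr, nc, well_center, well_radius)] <- bgval
  cropped <- intensity_image(px,
    bit_depth = attr(image, "bit_depth"),
    polarity = img_polarity(image)
  )
  particle_stats(binarize(cropped, threshold, foreground),
    min_size = min_size, connectivity = connectivity
  )
}
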