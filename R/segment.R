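#' Circular colony region
#'
#' Describes the outlined colony footprint as a closed disk: a pixel belongs
#' to the region when its center lies within `radius` of `center`. `area` is
#' the number of pixels so counted (the discrete equivalent of pi * r^2).
#'
#' @param center Numeric length-2 `(row, col)`, 1-based.
#' @param radius Radius in pixels.
#' @param nrow,ncol Dimensions of the image the region lives in (used to
#'   compute the pixel-count area and validate bounds).
#' @return A `colony_region` list with fields `center`, `radius`, `area`.
#' @export
colony_region <- function(center, radius, nrow, ncol) {
  stopifnot(length(center) == 2, radius > 0)
  area <- sum(disk_mask(nrow, ncol, center, radius))
  if (area == 0) abort("region has zero area")
  structure(list(center = as.numeric(center), radius = as.numeric(radius), area = area),
    class = "colony_region"
  )
}

#' @export
print.colony_region <- function(x, ...) {
  cat(sprintf(
    "<colony_region> center (%.1f, %.1f), radius %.2f px, area %d px^2\n",
    x$center[1], x$center[2], x$radius, x$area
  ))
  invisible(x)
}

#' Segment the colony footprint of a pre-wash image
#'
#' Outlines the colony near a user-supplied hint and fits a circle to it:
#' the image is thresholded (Otsu's method by default), connected foreground
#' components are labeled, components within `search_radius` of the hint are
#' candidates, and the candidate whose centroid is nearest the hint is
#' selected. The returned region is the equivalent circle of that component
#' (centroid center, radius `sqrt(n_pixels / pi)`), the automated stand-in
#' for a hand-drawn circular outline. Pass `manual` to bypass segmentation
#' entirely and reproduce a hand-picked circle.
#'
#' @param pre_wash An [intensity_image()] of colonies before washing, with
#'   colonies brighter than the background (invert beforehand if not).
#' @param hint_center Numeric `(row, col)` near the expected colony center.
#' @param search_radius Pixels; candidate components must come within this
#'   distance of the hint.
#' @param threshold Foreground threshold; `NULL` (default) uses Otsu's
#'   method on the image histogram.
#' @param manual Optional list with `center` and `radius` overriding the
#'   automatic outline.
#' @return A [colony_region()].
#' @examples
#' px <- matrix(0, 64, 64)
#' px[disk_region(64, 64, c(32, 32), 10)] <- 200
#' segment_colony(intensity_image(px), hint_center = c(30, 30), search_radius = 15)
#' @export
segment_colony <- function(pre_wash, hint_center, search_radius,
                           threshold = NULL, manual = NULL) {
  if (!inherits(pre_wash, "intensity_image")) pre_wash <- intensity_image(pre_wash)
  nr <- nrow(pre_wash)
  nc <- ncol(pre_wash)
  if (!is.null(manual)) {
    return(colony_region(manual$center, manual$radius, nr, nc))
  }
  if (hint_center[1] < 1 || hint_center[1] > nr || hint_center[2] < 1 || hint_center[2] > nc) {
    abort("`hint_center` lies outside the image")
  }
  if (search_radius <= 0) abort("`search_radius` must be positive")

  px <- unclass(pre_wash)
  if (is.null(threshold)) {
    if (min(px) == max(px)) abort("colony not found: image has no contrast")
    threshold <- EBImage::otsu(EBImage::Image(px / img_maxval(pre_wash))) * img_maxval(pre_wash)
  }
  fg <- px > threshold
  if (!any(fg)) abort("colony not found: empty foreground")

  labels <- label_components(fg, connectivity = 8)
  ids <- setdiff(unique(as.vector(labels)), 0L)
  rows <- row(labels)
  cols <- col(labels)
  # nearest-to-hint rule: candidate components must come within the search
  # radius; among candidates the nearest centroid wins, ties to the largest
  stats <- lapply(ids, function(id) {
    sel <- labels == id
    r <- rows[sel]
    c <- cols[sel]
    mind <- sqrt(min((r - hint_center[1])^2 + (c - hint_center[2])^2))
    list(
      id = id, n = sum(sel), cr = mean(r), cc = mean(c), mind = mind,
      cdist = sqrt((mean(r) - hint_center[1])^2 + (mean(c) - hint_center[2])^2)
    )
  })
  stats <- Filter(function(s) s$mind <= search_radius, stats)
  if (length(stats) == 0) abort("colony not found: no foreground component within search radius")
  ord <- order(
    vapply(stats, `[[`, numeric(1), "cdist"),
    -vapply(stats, `[[`, numeric(1), "n")
  )
  best <- stats[[ord[1]]]
  colony_region(c(best$cr, best$cc), sqrt(best$n / pi), nr, nc)
}

#' Linear indices of a closed disk within an image grid
#'
#' Convenience for building fixtures and masks with the same pixel-membership
#' rule the quantification uses.
#'
#' @param nrow,ncol Image dimensions.
#' @param center `(row, col)` center, 1-based.
#' @param radius Radius in pixels.
#' @return Logical matrix marking disk pixels.
#' @export
disk_region <- function(nrow, ncol, center, radius) {
  disk_mask(nrow, ncol, center, radius)
}
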