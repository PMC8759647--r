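#' Invasion index of a washed scar within a colony-derived region
#'
#' Places the colony circle over the (registered) post-wash scar image and
#' integrates the inverted scar intensity inside it. The invasion index is
#' that integrated intensity divided by colony area, which controls for
#' growth differences between strains: `invasion = scar_intensity / area`.
#'
#' @param scar An [intensity_image()] with polarity `"inverted"` (see
#'   [preprocess_scar_image()]); pre- and post-wash images are assumed
#'   pixel-registered, with `offset` available for a rigid translation.
#' @param region A [colony_region()] from [segment_colony()].
#' @param strain,environment,replicate Labels recorded in the output row.
#' @param offset Optional `(row, col)` translation applied to the region
#'   center before measuring.
#' @return A one-row tibble with columns `strain`, `environment`,
#'   `replicate`, `scar_intensity`, `colony_area`, `invasion`.
#' @examples
#' px <- matrix(5, 50, 50)
#' scar <- intensity_image(px, polarity = "inverted")
#' reg <- colony_region(c(25, 25), 8, 50, 50)
#' invasion_index(scar, reg, "WT", "YPD", 1)
#' @export
invasion_index <- function(scar, region, strain = NA_character_,
                           environment = NA_character_, replicate = NA_integer_,
                           offset = c(0, 0)) {
  if (!inherits(scar, "intensity_image")) scar <- intensity_image(scar, polarity = "inverted")
  if (img_polarity(scar) != "inverted") {
    abort("`scar` must have inverted polarity (run preprocess_scar_image first)")
  }
  stopifnot(inherits(region, "colony_region"))
  center <- region$center + offset
  nr <- nrow(scar)
  nc <- ncol(scar)
  if (center[1] - region$radius < 0.5 || center[1] + region$radius > nr + 0.5 ||
    center[2] - region$radius < 0.5 || center[2] + region$radius > nc + 0.5) {
    abort("region lies (partly) outside the scar image")
  }
  mask <- disk_mask(nr, nc, center, region$radius)
  area <- sum(mask)
  if (area == 0) abort("region has zero area")
  scar_intensity <- sum(unclass(scar)[mask])
  tibble(
    strain = as.character(strain), environment = as.character(environment),
    replicate = as.integer(replicate),
    scar_intensity = scar_intensity, colony_area = area,
    invasion = scar_intensity / area
  )
}

#' Quantify a layout of pre-/post-wash image pairs
#'
#' Batch pipeline: for every layout row, segment the colony on the pre-wash
#' image and measure the invasion index on the matching preprocessed
#' post-wash image.
#'
#' @param pre_wash,post_wash Named lists of [intensity_image()]s keyed by
#'   `image_id`; post-wash images must already carry inverted polarity
#'   (see [preprocess_scar_batch()]).
#' @param layout Tibble with columns `image_id`, `strain`, `environment`,
#'   `replicate`, `hint_row`, `hint_col`.
#' @param search_radius Passed to [segment_colony()].
#' @return A measurement tibble, one row per layout row (see
#'   [invasion_index()]).
#' @export
quantify_invasion <- function(pre_wash, post_wash, layout, search_radius = 50) {
  needed <- c("image_id", "strain", "environment", "replicate", "hint_row", "hint_col")
  missing <- setdiff(needed, names(layout))
  if (length(missing) > 0) {
    abort(paste0("layout is missing columns: ", paste(missing, collapse = ", ")))
  }
  purrr::pmap_dfr(layout, function(image_id, strain, environment, replicate,
                                   hint_row, hint_col, ...) {
    id <- as.character(image_id)
    if (is.null(pre_wash[[id]]) || is.null(post_wash[[id]])) {
      abort(sprintf("no image pair named '%s'", id))
    }
    region <- segment_colony(pre_wash[[id]], c(hint_row, hint_col), search_radius)
    invasion_index(post_wash[[id]], region, strain, environment, replicate)
  })
}

#' Wild-type-relative GEI matrix
#'
#' Collapses replicate invasion measurements into a strains-by-environments
#' table of relative invasion: per environment, each strain's replicate-mean
#' invasion divided by the wild-type replicate mean, so wild type is exactly
#' 1 in every environment with growth. Replicate spread is propagated as the
#' replicate standard deviation on the same normalized scale. Strain and
#' environment order follow first appearance in `measurements`.
#'
#' Cells listed in `no_growth` (and strain-environment combinations absent
#' from `measurements`) are flagged, never imputed: a washed plate cannot
#' distinguish no growth from no invasion, so the flag must come from
#' metadata.
#'
#' @param measurements Tibble with columns `strain`, `environment`,
#'   `replicate`, `invasion` (extra columns are ignored).
#' @param wild_type Label of the wild-type strain (default `"WT"`).
#' @param no_growth Optional tibble with columns `strain`, `environment`
#'   flagging cells where the strain did not grow.
#' @return A `gei_matrix`: a tibble with columns `strain`, `environment`,
#'   `rel_invasion`, `rel_sd`, `no_growth`, plus attributes `wild_type`,
#'   `strains`, `environments`. Use [as.matrix()] for the wide grid and
#'   [autoplot()] for the heat map.
#' @examples
#' m <- tibble::tibble(
#'   strain = rep(c("WT", "mut"), each = 3), environment = "YPD",
#'   replicate = rep(1:3, 2), invasion = c(2, 2, 2, 1, 1, 1)
#' )
#' relative_invasion_matrix(m, wild_type = "WT")
#' @export
relative_invasion_matrix <- function(measurements, wild_type = "WT", no_growth = NULL) {
  stopifnot(all(c("strain", "environment", "invasion") %in% names(measurements)))
  strains <- unique(measurements$strain)
  environments <- unique(measurements$environment)
  if (!wild_type %in% strains) abort(sprintf("wild type '%s' absent from measurements", wild_type))

  if (!is.null(no_growth)) {
    stopifnot(all(c("strain", "environment") %in% names(no_growth)))
    ng_key <- paste(no_growth$strain, no_growth$environment, sep = "\r")
  } else {
    ng_key <- character(0)
  }

  per_cell <- measurements %>%
    filter(!paste(.data$strain, .data$environment, sep = "\r") %in% ng_key) %>%
    group_by(.data$strain, .data$environment) %>%
    summarise(
      mean_invasion = mean(.data$invasion),
      sd_invasion = if (n() > 1) sd(.data$invasion) else NA_real_,
      .groups = "drop"
    )

  wt <- per_cell %>%
    filter(.data$strain == wild_type) %>%
    select("environment", wt_mean = "mean_invasion")
  growth_envs <- wt$environment
  if (any(wt$wt_mean == 0)) {
    bad <- wt$environment[wt$wt_mean == 0]
    abort(paste0(
      "undefined normalization: wild-type mean invasion is 0 in ",
      paste(bad, collapse = ", ")
    ))
  }

  grid <- tidyr::expand_grid(strain = strains, environment = environments)
  out <- grid %>%
    left_join(per_cell, by = c("strain", "environment")) %>%
    left_join(wt, by = "environment") %>%
    mutate(
      no_growth = is.na(.data$mean_invasion) |
        paste(.data$strain, .data$environment, sep = "\r") %in% ng_key |
        !.data$environment %in% growth_envs,
      rel_invasion = ifelse(.data$no_growth, NA_real_, .data$mean_invasion / .data$wt_mean),
      rel_sd = ifelse(.data$no_growth, NA_real_, .data$sd_invasion / .data$wt_mean)
    ) %>%
    select("strain", "environment", "rel_invasion", "rel_sd", "no_growth")

  new_gei_matrix(out, wild_type, strains, environments)
}

new_gei_matrix <- function(tbl, wild_type, strains, environments) {
  structure(as_tibble(tbl),
    wild_type = wild_type, strains = strains, environments = environments,
    class = c("gei_matrix", class(as_tibble(tbl)))
  )
}

#' Build a GEI matrix from an already-normalized long table
#'
#' For tables that were normalized elsewhere (e.g. read back from
#' `gei.csv`): columns `strain`, `environment`, `rel_invasion` and
#' optionally `rel_sd`, `no_growth`.
#'
#' @param tbl Long tibble of relative invasion values.
#' @param wild_type Wild-type label.
#' @return A `gei_matrix`.
#' @export
as_gei_matrix <- function(tbl, wild_type = "WT") {
  stopifnot(all(c("strain", "environment", "rel_invasion") %in% names(tbl)))
  if (!"rel_sd" %in% names(tbl)) tbl$rel_sd <- NA_real_
  if (!"no_growth" %in% names(tbl)) tbl$no_growth <- is.na(tbl$rel_invasion)
  new_gei_matrix(
    tbl[c("strain", "environment", "rel_invasion", "rel_sd", "no_growth")],
    wild_type, unique(tbl$strain), unique(tbl$environment)
  )
}

#' @export
as.matrix.gei_matrix <- function(x, ...) {
  strains <- attr(x, "strains")
  envs <- attr(x, "environments")
  m <- matrix(NA_real_, length(strains), length(envs), dimnames = list(strains, envs))
  m[cbind(match(x$strain, strains), match(x$environment, envs))] <- x$rel_invasion
  m
}

#' @method tidy gei_matrix
#' @export
tidy.gei_matrix <- function(x, ...) {
  as_tibble(unclass_keep_tbl(x))
}

#' @method glance gei_matrix
#' @export
glance.gei_matrix <- function(x, ...) {
  tibble(
    n_strains = length(attr(x, "strains")),
    n_environments = length(attr(x, "environments")),
    wild_type = attr(x, "wild_type"),
    n_no_growth = sum(x$no_growth)
  )
}

unclass_keep_tbl <- function(x) {
  class(x) <- setdiff(class(x), c("gei_matrix", "gei_ranking"))
  attr(x, "wild_type") <- NULL
  attr(x, "strains") <- NULL
  attr(x, "environments") <- NULL
  x
}
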