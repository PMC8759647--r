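#' Diverging GEI heat-map color mapping
#'
#' Pure color mapping used by the heat-map renderers: relative invasion 1.0
#' (same as wild type) is white; values below 1 ramp linearly from white to
#' full red at 0 (less invasion); values above 1 ramp from white to full
#' blue at `cap` (more invasion); no-growth cells are black.
#'
#' @param rel_invasion Numeric vector of wild-type-relative invasion values.
#' @param no_growth Logical vector (recycled) flagging no-growth cells.
#' @param cap Relative invasion mapped to full blue (default 2; larger
#'   values are clamped).
#' @return Character vector of hex colors.
#' @examples
#' gei_color(c(0, 0.5, 1, 1.5, 2))
#' @export
gei_color <- function(rel_invasion, no_growth = FALSE, cap = 2) {
  stopifnot(cap > 1)
  no_growth <- rep_len(no_growth, length(rel_invasion))
  v <- pmin(pmax(rel_invasion, 0), cap)
  below <- !is.na(v) & v <= 1
  above <- !is.na(v) & v > 1
  r <- g <- b <- rep(NA_real_, length(v))
  # white -> red as value drops 1 -> 0
  r[below] <- 1
  g[below] <- v[below]
  b[below] <- v[below]
  # white -> blue as value rises 1 -> cap
  t <- (v[above] - 1) / (cap - 1)
  r[above] <- 1 - t
  g[above] <- 1 - t
  b[above] <- 1
  out <- rep(NA_character_, length(v))
  ok <- !is.na(r)
  out[ok] <- grDevices::rgb(r[ok], g[ok], b[ok])
  out[no_growth | is.na(rel_invasion)] <- "#000000"
  out
}

#' Render a GEI matrix as a raster heat map
#'
#' Writes a PNG with one `cell_size` x `cell_size` block per
#' strain-by-environment cell, colored by [gei_color()]: white = same
#' invasion as wild type, red ramp = less, blue ramp = more, black = no
#' growth. Strains run down the rows, environments across the columns.
#'
#' @param matrix A `gei_matrix` (see [relative_invasion_matrix()]).
#' @param out_path PNG output path.
#' @param cell_size Pixels per cell.
#' @param cap Passed to [gei_color()].
#' @return `out_path`, invisibly.
#' @export
render_gei_heatmap <- function(matrix, out_path, cell_size = 20, cap = 2) {
  m <- as.matrix(matrix)
  ng <- matrix(FALSE, nrow(m), ncol(m))
  ng[cbind(
    match(matrix$strain, rownames(m)),
    match(matrix$environment, colnames(m))
  )] <- matrix$no_growth
  cols <- gei_color(as.vector(m), as.vector(ng), cap = cap)
  rgbv <- grDevices::col2rgb(cols) / 255
  arr <- array(0, c(nrow(m), ncol(m), 3))
  for (ch in 1:3) arr[, , ch] <- matrix(rgbv[ch, ], nrow(m), ncol(m))
  big <- arr[rep(seq_len(nrow(m)), each = cell_size),
    rep(seq_len(ncol(m)), each = cell_size), ,
    drop = FALSE
  ]
  ok <- tryCatch(
    {
      png::writePNG(big, out_path)
      TRUE
    },
    error = function(e) FALSE
  )
  if (!ok) abort(sprintf("cannot write heat map to '%s'", out_path))
  invisible(out_path)
}

#' @rdname render_gei_heatmap
#' @param object A `gei_matrix`.
#' @param ... Ignored.
#' @method autoplot gei_matrix
#' @export
autoplot.gei_matrix <- function(object, cap = 2, ...) {
  df <- tidy(object) %>%
    mutate(
      fill = gei_color(.data$rel_invasion, .data$no_growth, cap = cap),
      strain = factor(.data$strain, levels = rev(attr(object, "strains"))),
      environment = factor(.data$environment, levels = attr(object, "environments"))
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$environment, .data$strain)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$fill), color = "grey40") +
    ggplot2::scale_fill_identity() +
    ggplot2::labs(
      x = "Environment", y = "Strain",
      title = "Relative invasion (white = wild type, red = less, blue = more, black = no growth)"
    ) +
    ggplot2::theme_minimal()
}
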