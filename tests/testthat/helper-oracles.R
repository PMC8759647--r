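# Independent brute-force oracles used across the suite. These deliberately
# re-derive results pixel-by-pixel / element-by-element, sharing nothing with
# the package implementation beyond input parameters.

# grayscale erosion/dilation/opening with an arbitrary 0/1 kernel; pixels
# falling outside the image are skipped (not padded)
oracle_morph <- function(px, kern, op = min) {
  nr <- nrow(px); nc <- ncol(px)
  kr <- (nrow(kern) - 1) / 2; kc <- (ncol(kern) - 1) / 2
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      vals <- c()
      for (di in -kr:kr) {
        for (dj in -kc:kc) {
          if (kern[di + kr + 1, dj + kc + 1] == 0) next
          ii <- i + di; jj <- j + dj
          if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) vals <- c(vals, px[ii, jj])
        }
      }
      out[i, j] <- op(vals)
    }
  }
  out
}

oracle_opening <- function(px, kern) {
  oracle_morph(oracle_morph(px, kern, min), kern, max)
}

# sum and area of a closed disk by explicit pixel loop
oracle_disk_sum <- function(px, center, radius) {
  s <- 0; n <- 0L
  for (i in seq_len(nrow(px))) {
    for (j in seq_len(ncol(px))) {
      if ((i - center[1])^2 + (j - center[2])^2 <= radius^2 + 1e-9) {
        s <- s + px[i, j]; n <- n + 1L
      }
    }
  }
  list(sum = s, area = n)
}

# horizontal band profile: per-column mean over band_height centered rows
oracle_band_profile <- function(px, band_height) {
  s <- nrow(px)
  r0 <- floor((s - band_height) / 2) + 1
  rows <- r0:(r0 + band_height - 1)
  vapply(seq_len(ncol(px)), function(j) mean(px[rows, j]), numeric(1))
}

# stack-based flood-fill connected-component labeling
oracle_flood_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 8) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1), c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  cur <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!mask[i, j] || lab[i, j] > 0) next
      cur <- cur + 1L
      stack <- list(c(i, j)); lab[i, j] <- cur
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        for (o in offs) {
          ii <- p[1] + o[1]; jj <- p[2] + o[2]
          if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && lab[ii, jj] == 0) {
            lab[ii, jj] <- cur
            stack[[length(stack) + 1]] <- c(ii, jj)
          }
        }
      }
    }
  }
  lab
}

# threshold counts and composite score by exhaustive triple loop
oracle_threshold_counts <- function(relmat, thresholds) {
  out <- matrix(0L, nrow(relmat), length(thresholds),
    dimnames = list(rownames(relmat), NULL)
  )
  for (i in seq_len(nrow(relmat))) {
    for (e in seq_len(ncol(relmat))) {
      for (t in seq_along(thresholds)) {
        v <- relmat[i, e]
        if (!is.na(v) && v <= thresholds[t]) out[i, t] <- out[i, t] + 1L
      }
    }
  }
  out
}

# two-sided permutation test for a difference in means
oracle_perm_p <- function(a, b, n_perm = 2000, seed = 1) {
  obs <- abs(mean(a) - mean(b))
  pool <- c(a, b); na <- length(a)
  hits <- 0L
  set.seed(seed)
  for (k in seq_len(n_perm)) {
    idx <- sample(length(pool), na)
    if (abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-12) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

# disk image fixture
make_disk_px <- function(size, center, radius, value, background = 0) {
  px <- matrix(background, size, size)
  for (i in seq_len(size)) {
    for (j in seq_len(size)) {
      if ((i - center[1])^2 + (j - center[2])^2 <= radius^2 + 1e-9) px[i, j] <- value
    }
  }
  px
}
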