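test_that("preprocessing removes flat background and isolates bright signal", {
  # constant field: no foreground anywhere
  flat <- intensity_image(matrix(37, 32, 32))
  out <- preprocess_scar_image(flat, background_radius = 5)
  expect_true(all(out == 0))
  expect_identical(attr(out, "polarity"), "inverted")

  # constant background b plus one bright 3x3 patch of b + k: the opening
  # removes the patch, so the output is zero outside and flat on the patch
  px <- matrix(40, 48, 48)
  px[20:22, 30:32] <- 40 + 90
  out <- preprocess_scar_image(intensity_image(px),
    background_radius = 6, contrast_percentiles = c(0, 100)
  )
  patch <- unclass(out)[20:22, 30:32]
  expect_true(all(patch > 0))
  expect_equal(max(patch), min(patch))
  outside <- unclass(out)
  outside[20:22, 30:32] <- 0
  expect_true(all(outside == 0))
})

test_that("background estimate equals a pixel-by-pixel morphological opening", {
  set.seed(11)
  px <- matrix(5, 30, 30)
  blobs <- cbind(sample(4:27, 6), sample(4:27, 6))
  for (i in seq_len(nrow(blobs))) {
    px[blobs[i, 1] + (-1:0), blobs[i, 2] + (-1:0)] <- 5 + sample(50:150, 1)
  }
  radius <- 4
  kern <- EBImage::makeBrush(2 * radius + 1, "disc")
  expected_bg <- oracle_opening(px, kern)
  got_bg <- geiplast:::morph_open(px, radius, 255)
  expect_equal(unname(got_bg), expected_bg, tolerance = 1e-10)
})

test_that("double preprocessing equals single application up to contrast rescale", {
  # sparse bright pixels on a flat background: the opening removes them all,
  # so a second pass adds nothing beyond the rescale
  set.seed(7)
  px <- matrix(20, 32, 32)
  idx <- cbind(sample(3:30, 8), sample(3:30, 8))
  px[idx] <- 20 + sample(40:120, 8, replace = TRUE)
  once <- preprocess_scar_image(intensity_image(px),
    background_radius = 3, contrast_percentiles = c(0, 100)
  )
  again_input <- intensity_image(unclass(once), polarity = "raw")
  twice <- preprocess_scar_image(again_input,
    background_radius = 3, contrast_percentiles = c(0, 100)
  )
  rescaled_once <- geiplast:::contrast_rescale(unclass(once), c(0, 100), 255)
  expect_equal(unclass(twice), rescaled_once, tolerance = 1e-9)
})

test_that("preprocessing validates its inputs", {
  img <- intensity_image(matrix(1, 10, 10))
  expect_error(preprocess_scar_image(img, background_radius = 20), "dimension")
  expect_error(preprocess_scar_image(img, background_radius = 0), "positive")
  expect_error(
    preprocess_scar_image(img, background_radius = 2, contrast_percentiles = c(99, 1)),
    "percentiles"
  )
  inv <- intensity_image(matrix(1, 10, 10), polarity = "inverted")
  expect_error(preprocess_scar_image(inv, background_radius = 2), "inverted")
  expect_error(intensity_image(matrix(1:2, 1)), NA)
  expect_error(intensity_image(matrix(300, 2, 2), bit_depth = 8), "\\[0, 255\\]")
})

test_that("batch preprocessing applies one shared parameter set", {
  imgs <- list(a = intensity_image(matrix(10, 20, 20)), b = intensity_image(matrix(30, 20, 20)))
  out <- preprocess_scar_batch(imgs, background_radius = 3)
  expect_named(out, c("a", "b"))
  log <- attr(out, "run_log")
  expect_equal(log$background_radius, 3)
  expect_equal(log$n_images, 2)
})

test_that("segmentation recovers an exact disk and honors the hint", {
  px <- make_disk_px(200, c(100, 100), 30, 200)
  reg <- segment_colony(intensity_image(px), c(95, 105), search_radius = 40)
  expect_lt(max(abs(reg$center - c(100, 100))), 1)
  expect_lt(abs(reg$radius - 30), 1)
  expect_equal(reg$area, oracle_disk_sum(px, reg$center, reg$radius)$area)

  # two disks: the component nearest the hint wins even if smaller
  px2 <- make_disk_px(200, c(60, 60), 10, 200)
  px2 <- pmax(px2, make_disk_px(200, c(140, 140), 35, 200))
  reg2 <- segment_colony(intensity_image(px2), c(63, 58), search_radius = 25)
  expect_lt(max(abs(reg2$center - c(60, 60))), 1.5)
  expect_lt(abs(reg2$radius - 10), 1.5)

  expect_error(
    segment_colony(intensity_image(matrix(0, 50, 50)), c(25, 25), 10),
    "colony not found"
  )

  manual <- segment_colony(intensity_image(px), c(1, 1), 5,
    manual = list(center = c(100, 100), radius = 30)
  )
  expect_equal(manual$radius, 30)
})

test_that("invasion index is intensity / area and matches a pixel-loop oracle", {
  scar <- intensity_image(matrix(5, 60, 60), polarity = "inverted")
  reg <- colony_region(c(30, 30), 7.97, 60, 60) # radius chosen for area ~ 200
  m <- invasion_index(scar, reg, "WT", "YPD", 1)
  expect_equal(m$invasion, m$scar_intensity / m$colony_area)
  expect_equal(m$invasion, 5)

  zero <- invasion_index(
    intensity_image(matrix(0, 60, 60), polarity = "inverted"), reg, "WT", "YPD", 1
  )
  expect_equal(zero$invasion, 0)

  set.seed(21)
  px <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64)
  reg2 <- colony_region(c(33, 30), 12, 64, 64)
  got <- invasion_index(intensity_image(px, polarity = "inverted"), reg2)
  want <- oracle_disk_sum(px, c(33, 30), 12)
  expect_equal(got$scar_intensity, want$sum)
  expect_equal(got$colony_area, want$area)
  expect_equal(got$invasion, want$sum / want$area)

  # linearity: scaling all scar pixels by k scales invasion by exactly k
  k <- 0.37
  got_k <- invasion_index(intensity_image(px * k, polarity = "inverted"), reg2)
  expect_equal(got_k$invasion, got$invasion * k)

  expect_error(
    invasion_index(intensity_image(px, polarity = "inverted"), colony_region(c(5, 5), 12, 64, 64)),
    "outside"
  )
  expect_error(invasion_index(intensity_image(px), reg2), "polarity")
})

test_that("invasion index is translation invariant up to discretization", {
  scar <- make_disk_px(120, c(40, 40), 18, 130)
  m1 <- invasion_index(intensity_image(scar, polarity = "inverted"),
    colony_region(c(40, 40), 25, 120, 120))
  # the same colony + scar pattern moved rigidly within the frame
  shifted <- make_disk_px(120, c(70, 80), 18, 130)
  m2 <- invasion_index(intensity_image(shifted, polarity = "inverted"),
    colony_region(c(70, 80), 25, 120, 120))
  expect_lt(abs(m2$invasion / m1$invasion - 1), 0.01)
})

test_that("relative invasion normalizes to wild type = 1 with propagated spread", {
  m <- tibble::tibble(
    strain = rep(c("WT", "mut"), each = 3), environment = "YPD",
    replicate = rep(1:3, 2), invasion = c(2, 2, 2, 1, 1, 1)
  )
  gm <- relative_invasion_matrix(m)
  expect_equal(gm$rel_invasion[gm$strain == "WT"], 1)
  expect_equal(gm$rel_invasion[gm$strain == "mut"], 0.5)

  # mutant equal to WT; WT rel_sd = replicate SD / mean
  m2 <- tibble::tibble(
    strain = rep(c("WT", "mut"), each = 3), environment = "E",
    replicate = rep(1:3, 2), invasion = c(1.8, 2.0, 2.2, 1.8, 2.0, 2.2)
  )
  gm2 <- relative_invasion_matrix(m2)
  expect_equal(gm2$rel_invasion, c(1, 1))
  expect_equal(gm2$rel_sd[gm2$strain == "WT"], sd(c(1.8, 2, 2.2)) / 2)
})

test_that("relative invasion matches a spreadsheet-style oracle on random tables", {
  set.seed(5)
  grid <- expand.grid(
    strain = c("WT", "a", "b"), environment = c("E1", "E2"),
    replicate = 1:3, stringsAsFactors = FALSE
  )
  grid$invasion <- runif(nrow(grid), 0.5, 3)
  gm <- relative_invasion_matrix(tibble::as_tibble(grid))
  for (s in c("WT", "a", "b")) {
    for (e in c("E1", "E2")) {
      reps <- grid$invasion[grid$strain == s & grid$environment == e]
      wtreps <- grid$invasion[grid$strain == "WT" & grid$environment == e]
      cell <- gm[gm$strain == s & gm$environment == e, ]
      expect_equal(cell$rel_invasion, mean(reps) / mean(wtreps))
      expect_equal(cell$rel_sd, sd(reps) / mean(wtreps))
    }
  }

  # wild-type mean of zero in a growth environment is an error, not Inf
  bad <- grid
  bad$invasion[bad$strain == "WT" & bad$environment == "E1"] <- 0
  expect_error(relative_invasion_matrix(tibble::as_tibble(bad)), "undefined normalization")
})

test_that("no-growth cells are flagged and excluded, not imputed", {
  grid <- expand.grid(
    strain = c("WT", "a"), environment = c("E1", "E2"),
    replicate = 1:2, stringsAsFactors = FALSE
  )
  grid$invasion <- 1
  gm <- relative_invasion_matrix(tibble::as_tibble(grid),
    no_growth = tibble::tibble(strain = "a", environment = "E2")
  )
  cell <- gm[gm$strain == "a" & gm$environment == "E2", ]
  expect_true(cell$no_growth)
  expect_true(is.na(cell$rel_invasion))
  expect_equal(glance(gm)$n_no_growth, 1L)
})

test_that("heat-map colors follow the white/red/blue/black convention", {
  expect_equal(gei_color(1), "#FFFFFF")
  expect_equal(gei_color(0), "#FF0000") # full-red endpoint
  expect_equal(gei_color(2, cap = 2), "#0000FF") # full-blue at the cap
  expect_equal(gei_color(5, cap = 2), "#0000FF") # clamped beyond the cap
  expect_equal(gei_color(1, no_growth = TRUE), "#000000")
  # midpoints interpolate linearly
  expect_equal(gei_color(0.5), grDevices::rgb(1, 0.5, 0.5))

  gm <- as_gei_matrix(tibble::tibble(
    strain = c("WT", "a"), environment = "E1", rel_invasion = c(1, 0.4)
  ))
  path <- tempfile(fileext = ".png")
  render_gei_heatmap(gm, path, cell_size = 4)
  expect_true(file.exists(path))
  arr <- png::readPNG(path)
  expect_equal(dim(arr)[1:2], c(8L, 4L))
  expect_equal(arr[1, 1, ], c(1, 1, 1)) # WT cell white
})
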