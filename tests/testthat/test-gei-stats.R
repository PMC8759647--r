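make_rel_matrix <- function(relmat, wild_type = "WT") {
  # build a gei_matrix from a mutant x environment grid of relative values
  long <- tidyr::expand_grid(
    strain = c(wild_type, rownames(relmat)), environment = colnames(relmat)
  )
  long$rel_invasion <- 1
  mut <- long$strain != wild_type
  long$rel_invasion[mut] <- relmat[cbind(long$strain[mut], long$environment[mut])]
  as_gei_matrix(long, wild_type = wild_type)
}

test_that("threshold counts and composite scores follow the ladder definition", {
  relmat <- matrix(0.05, 1, 11, dimnames = list("m", paste0("E", 1:11)))
  rk <- rank_regulators(make_rel_matrix(relmat))
  expect_equal(unname(unlist(rk[1, paste0("count_le", c("75", "50", "25", "20", "15", "10"))])),
    rep(11, 6))
  expect_equal(rk$composite_score, 66)
  expect_equal(rk$mean_rel_invasion, 0.05)

  same <- matrix(1, 1, 11, dimnames = list("m", paste0("E", 1:11)))
  rk0 <- rank_regulators(make_rel_matrix(same))
  expect_equal(rk0$composite_score, 0)
})

test_that("ranking matches an exhaustive double-loop oracle on random matrices", {
  set.seed(41)
  thresholds <- c(0.75, 0.50, 0.25, 0.20, 0.15, 0.10)
  relmat <- matrix(runif(5 * 11, 0, 1.4), 5, 11,
    dimnames = list(paste0("mut", 1:5), paste0("E", 1:11))
  )
  rk <- rank_regulators(make_rel_matrix(relmat))
  want <- oracle_threshold_counts(relmat, thresholds)
  for (s in rownames(relmat)) {
    got <- unname(unlist(rk[rk$strain == s, grep("^count_le", names(rk))]))
    expect_equal(got, unname(want[s, ]))
    expect_equal(rk$composite_score[rk$strain == s], sum(want[s, ]))
    expect_equal(rk$mean_rel_invasion[rk$strain == s], mean(relmat[s, ]))
  }
  # rank of record: descending composite, ties by ascending mean
  ord <- order(-rowSums(want), rowMeans(relmat), rownames(relmat))
  expect_equal(rk$strain, rownames(relmat)[ord])
  expect_equal(rk$rank, 1:5)
})

test_that("counts are monotone down the threshold ladder and order invariant", {
  set.seed(42)
  for (i in 1:20) {
    relmat <- matrix(runif(4 * 8, 0, 1.3), 4, 8,
      dimnames = list(paste0("m", 1:4), paste0("E", 1:8))
    )
    rk <- rank_regulators(make_rel_matrix(relmat))
    counts <- as.matrix(rk[, grep("^count_le", names(rk))])
    expect_true(all(counts[, -1] <= counts[, -ncol(counts)] + 1e-9))
    expect_true(all(counts >= 0 & counts <= 8))

    # permuting strains and environments leaves composite scores unchanged
    perm <- relmat[sample(nrow(relmat)), sample(ncol(relmat)), drop = FALSE]
    rk2 <- rank_regulators(make_rel_matrix(perm))
    expect_equal(
      rk2$composite_score[match(rk$strain, rk2$strain)],
      rk$composite_score
    )
  }
})

test_that("no-growth environments are excluded from ranking", {
  relmat <- matrix(c(0.1, 0.1, NA), 1, 3, dimnames = list("m", c("E1", "E2", "E3")))
  long <- make_rel_matrix(matrix(0.1, 1, 3, dimnames = dimnames(relmat)))
  long$rel_invasion[long$strain == "m" & long$environment == "E3"] <- NA
  long$no_growth[long$strain == "m" & long$environment == "E3"] <- TRUE
  rk <- rank_regulators(long)
  expect_equal(rk$n_environments, 2L)
  expect_equal(rk$composite_score, 12)
  expect_error(rank_regulators(long, include_environments = character(0)), "empty")
})

test_that("mean relative summaries handle the degenerate single-environment case", {
  relmat <- matrix(c(0.2, 0.4), 1, 2, dimnames = list("m", c("E1", "E2")))
  s <- mean_relative_summary(make_rel_matrix(relmat))
  expect_equal(s$mean_rel_invasion[s$strain == "m"], 0.3)
  expect_equal(s$sd[s$strain == "m"], sd(c(0.2, 0.4)))

  one <- mean_relative_summary(make_rel_matrix(relmat), include_environments = "E1")
  expect_equal(one$sd[one$strain == "m"], 0)
  expect_false(one$sd_defined[one$strain == "m"])
})

test_that("Dunnett comparisons control the null and detect a planted shift", {
  set.seed(51)
  null_groups <- list(WT = rnorm(6), a = rnorm(6), b = rnorm(6))
  null_groups <- lapply(null_groups, function(x) x - mean(x)) # identical means
  res <- compare_to_control(null_groups, "WT")
  expect_equal(nrow(res), 2)
  expect_true(all(res$p_adjusted > 0.9))
  expect_lt(glance(res)$f_statistic, 1e-10)

  set.seed(52)
  shifted <- list(WT = rnorm(10), hit = rnorm(10, 5), null = rnorm(10))
  res2 <- compare_to_control(shifted, "WT")
  expect_lt(res2$p_adjusted[res2$comparison == "hit - WT"], 0.001)
  # permutation oracle agrees the shift is beyond chance
  expect_lt(oracle_perm_p(shifted$hit, shifted$WT, 999, seed = 5), 0.005)
  # adjusted p never below raw p
  expect_true(all(res2$p_adjusted >= res2$p_raw - 1e-12))
  expect_true(all(res2$p_adjusted >= 0 & res2$p_adjusted <= 1))
})

test_that("Tukey all-pairs comparisons enumerate k(k-1)/2 contrasts", {
  set.seed(53)
  x <- rnorm(5)
  same <- list(a = x, b = x + rnorm(5, 0, 1e-8), c = x + rnorm(5, 0, 1e-8))
  res <- compare_all_pairs(lapply(same, function(v) v - mean(v) + 1))
  expect_equal(nrow(res), 3)
  expect_true(all(res$p_adjusted > 0.95))

  set.seed(54)
  groups <- list(a = rnorm(6), b = rnorm(6), c = rnorm(6), d = rnorm(6, 10))
  res2 <- compare_all_pairs(groups)
  expect_equal(nrow(res2), 6)
  hit <- grepl("d", res2$comparison)
  expect_true(all(res2$p_adjusted[hit] < 0.001))
  expect_true(all(res2$p_adjusted[!hit] > 0.05))
  expect_true(all(res2$p_adjusted >= res2$p_raw - 1e-12))
})

test_that("Student's t behaves at the null, under swap, and against permutation", {
  a <- c(1, 2, 3, 4)
  same <- students_t(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_raw, 1)

  set.seed(55)
  x <- rnorm(8)
  y <- rnorm(8, 1)
  expect_equal(students_t(x, y)$statistic, -students_t(y, x)$statistic)
  expect_equal(students_t(x, y)$p_raw, students_t(y, x)$p_raw)

  set.seed(56)
  for (i in 1:5) {
    x <- rnorm(20)
    y <- rnorm(20, 1)
    pt <- students_t(x, y)$p_raw
    pp <- oracle_perm_p(x, y, 2000, seed = i)
    expect_lt(abs(pt - pp), 0.05)
  }
})

test_that("invasion-size correlation is R^2 with degenerate inputs rejected", {
  x <- 1:10
  expect_equal(invasion_size_correlation(2 * x + 3, x), 1)
  set.seed(57)
  expect_lt(invasion_size_correlation(rnorm(1000), rnorm(1000)), 0.01)
  expect_error(invasion_size_correlation(rep(1, 5), 1:5), "constant")
  expect_error(invasion_size_correlation(1:3, 1:4), "length")
})

test_that("2^-delta-Ct expression follows cycle arithmetic and shift invariance", {
  expect_equal(rel_expression_2dct(15, 15)$rel_expression, 1)
  expect_equal(rel_expression_2dct(16, 15)$rel_expression, 0.5)
  set.seed(58)
  ct_t <- runif(10, 10, 30)
  ct_r <- runif(10, 10, 30)
  k <- 3.7
  expect_equal(
    rel_expression_2dct(ct_t + k, ct_r + k)$rel_expression,
    rel_expression_2dct(ct_t, ct_r)$rel_expression
  )
})

test_that("the qPCR pipeline averages in delta-Ct space and normalizes to wild type", {
  ct <- tidyr::expand_grid(
    gene = "FLO11", strain = c("WT", "mut"), condition = "YPD", replicate = 1:3
  )
  ct$ct_reference <- 15
  ct$ct_target <- ifelse(ct$strain == "WT", c(15, 15.5, 14.5), c(17, 17.5, 16.5))
  out <- summarize_qpcr(ct, "WT")
  # hand arithmetic: mean dCt WT = 0, mut = 2 -> expression 1 and 0.25
  expect_equal(out$rel_expression[out$strain == "WT"], 1)
  expect_equal(out$rel_expression[out$strain == "mut"], 0.25)
  expect_equal(out$rel_to_wt[out$strain == "mut"], 0.25)
  expect_error(summarize_qpcr(ct, "nope"), "absent")
})

test_that("morphometry uses max/min ratios and distal-bud percentages", {
  suppressWarnings({
    expect_equal(morphometry(4, 2, c(distal = 50, proximal = 25, equatorial = 25))$lw_mean, 2)
    expect_equal(morphometry(2, 4, c(distal = 50, proximal = 25, equatorial = 25))$lw_mean, 2)
  })
  m <- morphometry(runif(30, 4, 8), runif(30, 2, 4),
    c(distal = 50, proximal = 25, equatorial = 25)
  )
  expect_equal(m$distal_pct, 50)
  expect_equal(m$n_buds, 100L)
  expect_true(all(pmax(4, 2) / pmin(4, 2) >= 1))
  expect_warning(morphometry(rep(4, 5), rep(2, 5), c(distal = 60, proximal = 30, equatorial = 30)),
    "25 cells")
  expect_warning(morphometry(rep(4, 30), rep(2, 30), c(distal = 10, proximal = 5, equatorial = 5)),
    "100 buds")

  set.seed(59)
  l <- runif(40, 1, 10)
  w <- runif(40, 1, 10)
  got <- suppressWarnings(morphometry(l, w, c(distal = 120, proximal = 40, equatorial = 40)))
  expect_equal(got$lw_mean, mean(pmax(l, w) / pmin(l, w)))
  expect_equal(got$lw_sd, sd(pmax(l, w) / pmin(l, w)))
  expect_equal(got$distal_pct, 100 * 120 / 200)
})
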