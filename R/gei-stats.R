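#' Rank regulators by threshold counts across environments
#'
#' Ranks each mutant's overall contribution to invasive growth across the
#' included environments. Two summaries are computed per mutant: the mean
#' relative invasion across environments (with its sample SD), and, because
#' that mean can be highly variable, the number of environments in which the
#' mutant fell to or below each of a ladder of thresholds of wild-type
#' invasion (default 75, 50, 25, 20, 15 and 10 percent; comparison is
#' inclusive, `<=`). The counts are necessarily non-increasing down the
#' ladder. The composite score is the sum of the six counts; rank 1 is the
#' strongest regulator (highest composite, ties broken by ascending mean
#' relative invasion, then label).
#'
#' No-growth cells are excluded from both summaries, and environments can be
#' excluded wholesale (e.g. an invasion-inhibiting environment where nothing
#' invades) via `include_environments`.
#'
#' @param matrix A `gei_matrix` (see [relative_invasion_matrix()]).
#' @param include_environments Environments to include; default all in the
#'   matrix.
#' @param thresholds Decreasing vector of relative-invasion thresholds.
#' @return A `gei_ranking` tibble: `strain`, `mean_rel_invasion`, `sd`,
#'   `n_environments`, one `count_le*` column per threshold,
#'   `composite_score`, `rank`, ordered by rank. The wild-type reference
#'   strain is not ranked.
#' @examples
#' gm <- as_gei_matrix(tibble::tibble(
#'   strain = rep(c("WT", "a", "b"), each = 2),
#'   environment = rep(c("E1", "E2"), 3),
#'   rel_invasion = c(1, 1, 0.05, 0.1, 0.8, 1.0)
#' ))
#' rank_regulators(gm)
#' @export
rank_regulators <- function(matrix, include_environments = NULL,
                            thresholds = c(0.75, 0.50, 0.25, 0.20, 0.15, 0.10)) {
  stopifnot(inherits(matrix, "gei_matrix"))
  envs <- include_environments %||% attr(matrix, "environments")
  if (length(envs) == 0) abort("empty environment set")
  missing <- setdiff(envs, attr(matrix, "environments"))
  if (length(missing) > 0) {
    abort(paste0("unknown environments: ", paste(missing, collapse = ", ")))
  }
  wt <- attr(matrix, "wild_type")

  cells <- matrix %>%
    filter(.data$environment %in% envs, !.data$no_growth, .data$strain != wt)

  counts <- cells %>%
    group_by(.data$strain) %>%
    summarise(
      mean_rel_invasion = mean(.data$rel_invasion),
      sd = if (n() > 1) sd(.data$rel_invasion) else NA_real_,
      n_environments = n(),
      !!!setNames(
        lapply(thresholds, function(th) {
          rlang::quo(sum(.data$rel_invasion <= !!th))
        }),
        paste0("count_le", sub("^0\\.", "", format(thresholds)))
      ),
      .groups = "drop"
    )
  count_cols <- paste0("count_le", sub("^0\\.", "", format(thresholds)))
  counts$composite_score <- rowSums(counts[count_cols])
  out <- counts %>%
    arrange(-.data$composite_score, .data$mean_rel_invasion, .data$strain) %>%
    mutate(rank = row_number())
  structure(out,
    thresholds = thresholds, wild_type = wt,
    class = c("gei_ranking", class(tibble()))
  )
}

#' @method tidy gei_ranking
#' @export
tidy.gei_ranking <- function(x, ...) as_tibble(unclass_keep_tbl(x))

#' @method glance gei_ranking
#' @export
glance.gei_ranking <- function(x, ...) {
  tibble(
    n_strains = nrow(x), n_thresholds = length(attr(x, "thresholds")),
    top_strain = x$strain[x$rank == 1]
  )
}

#' @method autoplot gei_ranking
#' @export
autoplot.gei_ranking <- function(object, ...) {
  df <- mutate(object, strain = factor(.data$strain, levels = rev(object$strain)))
  ggplot2::ggplot(df, ggplot2::aes(.data$composite_score, .data$strain)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(
      x = "Composite score (environments at or below each threshold, summed)",
      y = "Mutant", title = "Regulator ranking across environments"
    ) +
    ggplot2::theme_minimal()
}

#' Per-strain mean relative invasion across environments
#'
#' @inheritParams rank_regulators
#' @return Tibble with `strain`, `mean_rel_invasion`, `sd` (sample SD across
#'   environments; 0 with `sd_defined = FALSE` when only one environment
#'   contributes), `n_environments`.
#' @export
mean_relative_summary <- function(matrix, include_environments = NULL) {
  stopifnot(inherits(matrix, "gei_matrix"))
  envs <- include_environments %||% attr(matrix, "environments")
  if (length(envs) == 0) abort("empty environment set")
  matrix %>%
    filter(.data$environment %in% envs, !.data$no_growth) %>%
    group_by(.data$strain) %>%
    summarise(
      mean_rel_invasion = mean(.data$rel_invasion),
      sd = if (n() > 1) sd(.data$rel_invasion) else 0,
      sd_defined = n() > 1,
      n_environments = n(),
      .groups = "drop"
    )
}

#' Compare every mutant to a control by one-way ANOVA plus Dunnett's test
#'
#' Fits a one-way ANOVA across all groups and tests each non-control group
#' against the control with Dunnett's multiple-comparison adjustment
#' (single-step multivariate-t), the standard mutant-versus-wild-type
#' procedure. Confidence intervals are simultaneous at `ci_level`.
#'
#' @param groups Either a named list of replicate value vectors, or a tibble
#'   with columns `group` and `value`.
#' @param control_label Name of the control group (e.g. the wild type).
#' @param alpha Significance level recorded in the result (default 0.05).
#' @param ci_level Confidence level (default 0.95).
#' @param conf_int Compute simultaneous confidence intervals? Skipping them
#'   (`conf_int = FALSE`) is much faster when only p-values are needed, as
#'   in large simulation studies.
#' @return A `gei_stat` tibble, one row per comparison: `comparison`,
#'   `estimate`, `statistic`, `p_raw` (unadjusted), `p_adjusted`,
#'   `adjust_method`, `conf_low`, `conf_high`, `alpha`. The ANOVA F
#'   statistic and p-value are available via [glance()].
#' @examples
#' set.seed(1)
#' g <- list(WT = rnorm(6, 1), mutA = rnorm(6, 0.2), mutB = rnorm(6, 1))
#' compare_to_control(g, "WT")
#' @export
compare_to_control <- function(groups, control_label, alpha = 0.05, ci_level = 0.95,
                               conf_int = TRUE) {
  df <- groups_to_df(groups, first = control_label)
  fit <- aov(value ~ group, data = df)
  multcomp_table(fit, "Dunnett", alpha, ci_level, conf_int)
}

#' Compare all pairs of groups by one-way ANOVA plus Tukey's HSD
#'
#' All-pairs analogue of [compare_to_control()]: Tukey's multiple-comparison
#' adjustment over every pair of groups (`k * (k - 1) / 2` comparisons), the
#' standard mutant-versus-mutant procedure.
#'
#' @inheritParams compare_to_control
#' @return A `gei_stat` tibble, one row per pair (see
#'   [compare_to_control()]).
#' @export
compare_all_pairs <- function(groups, alpha = 0.05, ci_level = 0.95, conf_int = TRUE) {
  df <- groups_to_df(groups)
  fit <- aov(value ~ group, data = df)
  multcomp_table(fit, "Tukey", alpha, ci_level, conf_int)
}

groups_to_df <- function(groups, first = NULL) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("group", "value") %in% names(groups)))
    lv <- unique(as.character(groups$group))
    df <- data.frame(group = as.character(groups$group), value = groups$value)
  } else {
    stopifnot(is.list(groups), !is.null(names(groups)))
    lv <- names(groups)
    df <- data.frame(
      group = rep(names(groups), lengths(groups)),
      value = unlist(groups, use.names = FALSE)
    )
  }
  if (!is.null(first)) {
    if (!first %in% lv) abort(sprintf("control group '%s' absent", first))
    lv <- c(first, setdiff(lv, first))
  }
  if (length(lv) < 2) abort("need at least two groups")
  sizes <- table(df$group)
  if (any(sizes < 2)) abort("every group needs at least two replicates")
  df$group <- factor(df$group, levels = lv)
  df
}

# Shared Dunnett/Tukey machinery on a fitted one-way ANOVA. The
# multivariate-t quantiles behind the adjusted p-values are evaluated by
# randomized quasi-Monte-Carlo, so run them under a fixed, restored seed for
# reproducible output.
multcomp_table <- function(fit, type, alpha, ci_level, conf_int = TRUE) {
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(group = type))
  res <- with_preserved_seed(171717L, {
    adj <- summary(gl)
    raw <- summary(gl, test = multcomp::univariate())
    ci <- if (conf_int) stats::confint(gl, level = ci_level)
    list(adj = adj, raw = raw, ci = ci)
  })
  an <- summary(fit)[[1]]
  out <- tibble(
    comparison = names(res$adj$test$coefficients),
    estimate = as.numeric(res$adj$test$coefficients),
    statistic = as.numeric(res$adj$test$tstat),
    p_raw = as.numeric(res$raw$test$pvalues),
    p_adjusted = pmin(pmax(as.numeric(res$adj$test$pvalues),
                           as.numeric(res$raw$test$pvalues)), 1),
    adjust_method = tolower(type),
    conf_low = if (conf_int) as.numeric(res$ci$confint[, "lwr"]) else NA_real_,
    conf_high = if (conf_int) as.numeric(res$ci$confint[, "upr"]) else NA_real_,
    alpha = alpha
  )
  structure(out,
    f_statistic = an[["F value"]][1], f_p_value = an[["Pr(>F)"]][1],
    ci_level = ci_level,
    class = c("gei_stat", class(tibble()))
  )
}

#' @method tidy gei_stat
#' @export
tidy.gei_stat <- function(x, ...) as_tibble(`class<-`(x, class(tibble())))

#' @method glance gei_stat
#' @export
glance.gei_stat <- function(x, ...) {
  tibble(
    f_statistic = attr(x, "f_statistic") %||% NA_real_,
    f_p_value = attr(x, "f_p_value") %||% NA_real_,
    n_comparisons = nrow(x),
    ci_level = attr(x, "ci_level") %||% NA_real_
  )
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Student's t-test between two replicate sets
#'
#' Two-sided two-sample t-test (pooled variance by default, Welch optional),
#' returned in the same tabular shape as the multiple-comparison procedures.
#'
#' @param a,b Numeric replicate vectors.
#' @param var_equal Pooled variance (default `TRUE`)?
#' @param conf_level Confidence level.
#' @return A `gei_stat` tibble with one row (`adjust_method = "none"`,
#'   `p_adjusted = p_raw`).
#' @export
students_t <- function(a, b, var_equal = TRUE, conf_level = 0.95) {
  tt <- t.test(a, b, var.equal = var_equal, conf.level = conf_level)
  out <- tibble(
    comparison = "a - b",
    estimate = mean(a) - mean(b),
    statistic = unname(tt$statistic),
    p_raw = tt$p.value,
    p_adjusted = tt$p.value,
    adjust_method = "none",
    conf_low = tt$conf.int[1],
    conf_high = tt$conf.int[2],
    alpha = 1 - conf_level
  )
  structure(out,
    df = unname(tt$parameter), ci_level = conf_level,
    class = c("gei_stat", class(tibble()))
  )
}

#' Squared correlation between invasion and colony size
#'
#' Squared Pearson correlation, used to check that invasion indices are not
#' driven by colony size.
#'
#' @param invasion,colony_area Numeric vectors of equal length (>= 3).
#' @return The R^2 value.
#' @export
invasion_size_correlation <- function(invasion, colony_area) {
  if (length(invasion) != length(colony_area)) abort("inputs differ in length")
  if (length(invasion) < 3) abort("need at least 3 observations")
  if (sd(invasion) == 0 || sd(colony_area) == 0) {
    abort("correlation undefined for a constant input")
  }
  cor(invasion, colony_area)^2
}

#' Relative expression by the 2^-delta-Ct formula
#'
#' Delta-Ct is the difference in quantification cycles between the target
#' gene and the housekeeping reference (ACT1); relative expression is
#' `2^-delta_ct`, i.e. each extra cycle halves the inferred expression.
#'
#' @param ct_target,ct_reference Numeric Ct vectors of equal length.
#' @return Tibble with columns `ct_target`, `ct_reference`, `delta_ct`,
#'   `rel_expression`.
#' @examples
#' rel_expression_2dct(16, 15)$rel_expression # one extra cycle -> 0.5
#' @export
rel_expression_2dct <- function(ct_target, ct_reference) {
  if (length(ct_target) != length(ct_reference)) abort("Ct vectors differ in length")
  dct <- ct_target - ct_reference
  tibble(
    ct_target = ct_target, ct_reference = ct_reference,
    delta_ct = dct, rel_expression = 2^(-dct)
  )
}

#' Summarize a replicate Ct table into wild-type-relative expression
#'
#' Averages delta-Ct across biological replicates per gene, strain and
#' condition (averaging in delta-Ct space for log-scale symmetry), converts
#' to `2^-mean(delta_ct)`, and normalizes each gene-condition cell to the
#' wild-type strain (wild type = 1).
#'
#' @param ct_table Tibble with columns `gene`, `strain`, `condition`,
#'   `replicate`, `ct_target`, `ct_reference`.
#' @param wild_type Wild-type strain label.
#' @return Tibble with `gene`, `strain`, `condition`, `mean_delta_ct`,
#'   `rel_expression` (to the reference gene) and `rel_to_wt`.
#' @export
summarize_qpcr <- function(ct_table, wild_type = "WT") {
  needed <- c("gene", "strain", "condition", "ct_target", "ct_reference")
  stopifnot(all(needed %in% names(ct_table)))
  per <- ct_table %>%
    group_by(.data$gene, .data$strain, .data$condition) %>%
    summarise(
      mean_delta_ct = mean(.data$ct_target - .data$ct_reference),
      .groups = "drop"
    ) %>%
    mutate(rel_expression = 2^(-.data$mean_delta_ct))
  wt <- per %>%
    filter(.data$strain == wild_type) %>%
    select("gene", "condition", wt_expr = "rel_expression")
  if (nrow(wt) == 0) abort(sprintf("wild type '%s' absent from Ct table", wild_type))
  per %>%
    left_join(wt, by = c("gene", "condition")) %>%
    mutate(rel_to_wt = .data$rel_expression / .data$wt_expr) %>%
    select(-"wt_expr")
}

#' Morphometry summaries: length-to-width ratio and distal-bud percentage
#'
#' The per-cell elongation ratio always divides the larger measurement by
#' the smaller (`max / min`, so the ratio is >= 1 regardless of orientation).
#' The distal-bud percentage is distal buds over total buds, times 100.
#' Stated minima (25 cells for L/W, 100 buds for DB%) are enforced as
#' warnings, not errors.
#'
#' @param lengths,widths Per-cell measurements (equal length).
#' @param bud_positions Named counts with entries `distal`, `proximal`,
#'   `equatorial`.
#' @return Tibble with `n_cells`, `lw_mean`, `lw_sd`, `n_buds`,
#'   `distal_pct`.
#' @examples
#' morphometry(rep(4, 30), rep(2, 30), c(distal = 50, proximal = 25, equatorial = 25))
#' @export
morphometry <- function(lengths, widths, bud_positions) {
  if (length(lengths) != length(widths)) abort("lengths and widths differ in length")
  stopifnot(all(c("distal", "proximal", "equatorial") %in% names(bud_positions)))
  if (length(lengths) < 25) warn("fewer than 25 cells measured for the L/W ratio")
  total_buds <- sum(bud_positions[c("distal", "proximal", "equatorial")])
  if (total_buds < 100) warn("fewer than 100 buds counted for the distal-bud percentage")
  ratio <- pmax(lengths, widths) / pmin(lengths, widths)
  tibble(
    n_cells = length(ratio),
    lw_mean = mean(ratio),
    lw_sd = if (length(ratio) > 1) sd(ratio) else NA_real_,
    n_buds = as.integer(total_buds),
    distal_pct = 100 * bud_positions[["distal"]] / total_buds
  )
}
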