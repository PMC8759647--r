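#' Call a pathway's role in one environment
#'
#' A mutant significantly below wild type marks the deleted pathway as a
#' positive regulator of invasion in that environment; significantly above,
#' a negative regulator; otherwise no call. The test is a two-sided
#' Student's t by default; when a whole environment panel is tested at once
#' use [call_roles()], which applies Dunnett adjustment against the wild
#' type.
#'
#' @param mutant_reps,wt_reps Replicate invasion values (>= 2 each).
#' @param strain,environment Labels recorded in the output.
#' @param alpha Significance level.
#' @return A one-row tibble: `strain`, `environment`, `role` (one of
#'   `positive_regulator`, `negative_regulator`, `none`), `effect_size`
#'   (mutant mean relative to wild-type mean), `p_adjusted`.
#' @export
call_role <- function(mutant_reps, wt_reps, strain = NA_character_,
                      environment = NA_character_, alpha = 0.05) {
  if (length(mutant_reps) < 2 || length(wt_reps) < 2) {
    abort("need at least 2 replicates per group")
  }
  tt <- students_t(mutant_reps, wt_reps)
  role_row(strain, environment,
    p = tt$p_adjusted, alpha = alpha,
    mut_mean = mean(mutant_reps), wt_mean = mean(wt_reps)
  )
}

role_row <- function(strain, environment, p, alpha, mut_mean, wt_mean) {
  role <- if (p >= alpha) {
    "none"
  } else if (mut_mean < wt_mean) {
    "positive_regulator"
  } else {
    "negative_regulator"
  }
  tibble(
    strain = as.character(strain), environment = as.character(environment),
    role = role, effect_size = mut_mean / wt_mean, p_adjusted = p
  )
}

#' Call pathway roles for every mutant and environment of a measurement table
#'
#' Batched version of [call_role()]: per environment, every mutant is
#' compared to the wild type with Dunnett adjustment
#' ([compare_to_control()]).
#'
#' @param measurements Tibble with columns `strain`, `environment`,
#'   `invasion` (replicate rows).
#' @param wild_type Wild-type strain label.
#' @param alpha Significance level.
#' @return A tibble of role calls, one row per mutant-environment cell.
#' @export
call_roles <- function(measurements, wild_type = "WT", alpha = 0.05) {
  stopifnot(all(c("strain", "environment", "invasion") %in% names(measurements)))
  purrr::map_dfr(unique(measurements$environment), function(env) {
    sub <- filter(measurements, .data$environment == env)
    res <- compare_to_control(
      data.frame(group = sub$strain, value = sub$invasion), wild_type
    )
    means <- tapply(sub$invasion, sub$strain, mean)
    mut <- sub("\\s*-\\s*.*$", "", res$comparison)
    purrr::pmap_dfr(
      list(mut, res$p_adjusted),
      function(m, p) {
        role_row(m, env, p, alpha, means[[m]], means[[wild_type]])
      }
    )
  })
}

#' Detect a conditional role reversal
#'
#' A strain shows a conditional role reversal when the deleted pathway is a
#' positive regulator in at least one environment and a negative regulator
#' in at least one other -- promoting invasion in one setting and inhibiting
#' it in another.
#'
#' @param role_calls Role-call tibble for one or more strains (see
#'   [call_role()] / [call_roles()]); at least two environments per strain.
#' @return A tibble per strain: `strain`, `reversal` (logical), `witnesses`
#'   (string listing one positive-role and one negative-role environment, or
#'   `NA`).
#' @export
detect_role_reversal <- function(role_calls) {
  stopifnot(all(c("strain", "environment", "role") %in% names(role_calls)))
  role_calls %>%
    group_by(.data$strain) %>%
    summarise(
      reversal = any(.data$role == "positive_regulator") &&
        any(.data$role == "negative_regulator"),
      witnesses = if (any(.data$role == "positive_regulator") &&
        any(.data$role == "negative_regulator")) {
        paste0(
          "positive: ",
          paste(.data$environment[.data$role == "positive_regulator"], collapse = "/"),
          "; negative: ",
          paste(.data$environment[.data$role == "negative_regulator"], collapse = "/")
        )
      } else {
        NA_character_
      },
      n_environments = n(),
      .groups = "drop"
    )
}

#' Classify a double mutant as additive or redundant
#'
#' Operationalizes the additive-versus-redundant reading of double-mutant
#' plate assays. All four groups (wild type, both singles, the double) enter
#' a one-way ANOVA with Tukey-adjusted pairwise comparisons; the call uses
#' the double-versus-single contrasts:
#'
#' * `additive` -- the double is significantly below both singles (the
#'   pathways contribute separately);
#' * `redundant_to_a` -- the double is indistinguishable from single `a` and
#'   significantly below single `b` (symmetrically `redundant_to_b`);
#' * `redundant_to_both` -- the double is indistinguishable from both
#'   singles;
#' * `indeterminate` -- anything else, including a double significantly
#'   above a single.
#'
#' "Indistinguishable" is failure to reject equality at the adjusted alpha
#' -- an absence-of-evidence rule, flagged in the output. For a stricter
#' reading set `equivalence = TRUE`, which additionally requires a TOST
#' equivalence test (two one-sided t-tests at margin `margin` times the
#' wild-type mean) to succeed before calling redundancy.
#'
#' @param wt,single_a,single_b,double Replicate invasion values (>= 2 each).
#' @param alpha Significance level for the adjusted comparisons.
#' @param labels Length-2 labels for pathways a and b (cosmetic).
#' @param equivalence Require TOST equivalence for "same level" calls?
#' @param margin TOST equivalence margin as a fraction of the wild-type
#'   mean (default 0.25).
#' @return A one-row tibble: `pathway_a`, `pathway_b`, `call`,
#'   `p_double_vs_a`, `p_double_vs_b`, group means, `alpha`, `rule`.
#' @examples
#' set.seed(1)
#' classify_double_mutant(
#'   wt = rnorm(4, 1, 0.01), single_a = rnorm(4, 0.5, 0.01),
#'   single_b = rnorm(4, 0.5, 0.01), double = rnorm(4, 0.25, 0.01)
#' )$call # additive
#' @export
classify_double_mutant <- function(wt, single_a, single_b, double, alpha = 0.05,
                                   labels = c("a", "b"), equivalence = FALSE,
                                   margin = 0.25) {
  groups <- list(wt = wt, a = single_a, b = single_b, ab = double)
  if (any(lengths(groups) < 2)) abort("need at least 2 replicates per group (missing group?)")
  res <- compare_all_pairs(groups, alpha = alpha)
  pick <- function(g1, g2) {
    hit <- res$comparison %in% c(paste(g1, "-", g2), paste(g2, "-", g1))
    res$p_adjusted[hit]
  }
  p_ab_a <- pick("ab", "a")
  p_ab_b <- pick("ab", "b")
  m <- vapply(groups, mean, numeric(1))

  below_a <- p_ab_a < alpha && m[["ab"]] < m[["a"]]
  below_b <- p_ab_b < alpha && m[["ab"]] < m[["b"]]
  above_a <- p_ab_a < alpha && m[["ab"]] > m[["a"]]
  above_b <- p_ab_b < alpha && m[["ab"]] > m[["b"]]
  same_a <- p_ab_a >= alpha
  same_b <- p_ab_b >= alpha
  if (equivalence) {
    same_a <- same_a && tost_equivalent(double, single_a, margin * m[["wt"]], alpha)
    same_b <- same_b && tost_equivalent(double, single_b, margin * m[["wt"]], alpha)
  }

  call <- if (above_a || above_b) {
    "indeterminate"
  } else if (below_a && below_b) {
    "additive"
  } else if (same_a && below_b) {
    "redundant_to_a"
  } else if (same_b && below_a) {
    "redundant_to_b"
  } else if (same_a && same_b) {
    "redundant_to_both"
  } else {
    "indeterminate"
  }

  tibble(
    pathway_a = labels[1], pathway_b = labels[2], call = call,
    p_double_vs_a = p_ab_a, p_double_vs_b = p_ab_b,
    mean_wt = m[["wt"]], mean_a = m[["a"]], mean_b = m[["b"]],
    mean_double = m[["ab"]], alpha = alpha,
    rule = if (equivalence) "tost_equivalence" else "non_significance"
  )
}

# TOST: both one-sided tests must reject at alpha for the difference to be
# bounded by +/- margin.
tost_equivalent <- function(x, y, margin, alpha) {
  if (margin <= 0) {
    return(FALSE)
  }
  p_lower <- t.test(x, y, mu = -margin, alternative = "greater", var.equal = TRUE)$p.value
  p_upper <- t.test(x, y, mu = margin, alternative = "less", var.equal = TRUE)$p.value
  max(p_lower, p_upper) < alpha
}

#' Call a sensing versus non-sensing role between two environments
#'
#' Applicable only when the wild type itself changes invasion significantly
#' between the two environments. A mutant that shows no significant change
#' is a sensing candidate: the deleted pathway appears needed to sense the
#' difference between the environments. A mutant that still changes
#' significantly retains sensing (`non_sensing`).
#'
#' @param wt_env1,wt_env2 Wild-type replicate values in the two
#'   environments.
#' @param mutant_env1,mutant_env2 Mutant replicate values in the two
#'   environments.
#' @param alpha Significance level.
#' @return A one-row tibble: `call` (`sensing_candidate`, `non_sensing` or
#'   `not_applicable`), `p_wt`, `p_mutant`, and the four group means.
#' @export
call_sensing <- function(wt_env1, wt_env2, mutant_env1, mutant_env2, alpha = 0.05) {
  p_wt <- students_t(wt_env1, wt_env2)$p_adjusted
  p_mut <- students_t(mutant_env1, mutant_env2)$p_adjusted
  call <- if (p_wt >= alpha) {
    "not_applicable"
  } else if (p_mut >= alpha) {
    "sensing_candidate"
  } else {
    "non_sensing"
  }
  tibble(
    call = call, p_wt = p_wt, p_mutant = p_mut,
    mean_wt_env1 = mean(wt_env1), mean_wt_env2 = mean(wt_env2),
    mean_mutant_env1 = mean(mutant_env1), mean_mutant_env2 = mean(mutant_env2),
    alpha = alpha
  )
}
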