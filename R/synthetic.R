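#' Build a synthetic ground-truth world of pathway contributions
#'
#' A world fixes everything the generative model needs: environments,
#' pathways, a signed pathway-by-environment contribution matrix (negative =
#' inhibitory role, which plants conditional role reversals), shared
#' (redundant) contributions attached to pathway pairs, per-cell scar
#' patterns, per-environment baselines, the replicate noise level, and a
#' seed. Deletion strains are derived from the wild type by removing the
#' deleted pathway's private contribution; a shared contribution survives
#' until every pathway of its pair is deleted, so single deletions of a
#' redundant pair leave invasion unchanged and the double deletion removes
#' the shared term.
#'
#' Two combination rules are supported. `"additive"` (default) builds the
#' wild type up from the baseline: planted wild-type invasion is
#' `baseline_e * (1 + sum of weights + sum of shared terms)` and a deletion
#' subtracts its terms from the sum. `"deficit"` instead treats weights as
#' fractional losses relative to a wild type at `baseline_e`: a strain with
#' deleted set D has invasion `baseline_e * (1 - sum of weights over D -
#' shared terms fully inside D)`. The deficit rule can plant near-essential
#' effects for many pathways at once (fractional losses are not bounded by a
#' shared budget), which the additive rule cannot.
#'
#' @param environments Character vector of environment labels (>= 2).
#' @param pathways Character vector of pathway labels (>= 1); each pathway's
#'   single-deletion strain carries the pathway's name.
#' @param weights Pathways-by-environments numeric matrix of private
#'   contributions (dimnames optional; recycled scalars allowed).
#' @param shared Optional tibble `pathway_a`, `pathway_b`, `environment`,
#'   `weight` of shared (redundant) contributions.
#' @param double_mutants Optional tibble `pathway_a`, `pathway_b` naming
#'   double-deletion strains to carry (named `"A.B"`).
#' @param patterns Optional tibble `strain`, `environment`, `pattern`
#'   (`uniform`, `center` or `ring`); cells default to `uniform`.
#' @param baseline Per-environment baseline invasion (recycled).
#' @param replicate_noise_sd Replicate noise as a fraction of signal
#'   (multiplicative Gaussian; see `noise_model`). Default 0.1.
#' @param noise_model `"multiplicative"` (spread scales with signal, the
#'   plate-assay behavior) or `"additive"`.
#' @param combine `"additive"` or `"deficit"` (see Details).
#' @param no_growth Optional tibble `strain`, `environment` of cells where
#'   no growth occurs (no measurements are generated there).
#' @param seed Integer seed; the same seed and configuration regenerate
#'   identical outputs.
#' @return A `synthetic_world` list; see [planted_invasion()],
#'   [simulate_measurements()], [render_synthetic_plate()],
#'   [simulate_qpcr()].
#' @examples
#' w <- make_world(c("E1", "E2"), "P1", weights = matrix(1, 1, 2), seed = 7)
#' planted_invasion(w) # WT invasion 2, deletion invasion 1
#' @export
make_world <- function(environments, pathways, weights,
                       shared = NULL, double_mutants = NULL, patterns = NULL,
                       baseline = 1, replicate_noise_sd = 0.1,
                       noise_model = c("multiplicative", "additive"),
                       combine = c("additive", "deficit"),
                       no_growth = NULL, seed = 1L) {
  noise_model <- match.arg(noise_model)
  combine <- match.arg(combine)
  if (length(pathways) < 1) abort("need at least one pathway")
  if (length(environments) < 2) abort("need at least two environments")
  weights <- matrix(weights, length(pathways), length(environments),
    dimnames = list(pathways, environments)
  )
  baseline <- setNames(rep_len(baseline, length(environments)), environments)
  if (!is.null(shared)) {
    stopifnot(all(c("pathway_a", "pathway_b", "environment", "weight") %in% names(shared)))
    stopifnot(
      all(shared$pathway_a %in% pathways), all(shared$pathway_b %in% pathways),
      all(shared$environment %in% environments)
    )
  }

  strains <- tibble(strain = "WT", deleted = list(character(0)))
  strains <- bind_rows(strains, tibble(strain = pathways, deleted = lapply(pathways, identity)))
  if (!is.null(double_mutants)) {
    stopifnot(all(unlist(double_mutants[c("pathway_a", "pathway_b")]) %in% pathways))
    strains <- bind_rows(strains, tibble(
      strain = paste(double_mutants$pathway_a, double_mutants$pathway_b, sep = "."),
      deleted = purrr::map2(double_mutants$pathway_a, double_mutants$pathway_b, c)
    ))
  }

  world <- structure(
    list(
      environments = environments, pathways = pathways, weights = weights,
      shared = shared, strains = strains, patterns = patterns,
      baseline = baseline, replicate_noise_sd = replicate_noise_sd,
      noise_model = noise_model, combine = combine,
      no_growth = no_growth, seed = as.integer(seed)
    ),
    class = "synthetic_world"
  )
  planted <- planted_invasion(world)
  if (any(planted$invasion < -1e-9)) {
    abort("weights produce negative planted invasion")
  }
  world
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "<synthetic_world> %d pathways x %d environments, %d strains, %s/%s, noise sd %.2f, seed %d\n",
    length(x$pathways), length(x$environments), nrow(x$strains),
    x$combine, x$noise_model, x$replicate_noise_sd, x$seed
  ))
  invisible(x)
}

#' Planted (noise-free) invasion means of a synthetic world
#'
#' @param world A `synthetic_world`.
#' @return Tibble `strain`, `environment`, `invasion`, `rel_invasion`
#'   (relative to the planted wild type per environment).
#' @export
planted_invasion <- function(world) {
  stopifnot(inherits(world, "synthetic_world"))
  envs <- world$environments
  shared_sum <- function(env, deleted, deleted_only) {
    sh <- world$shared
    if (is.null(sh)) {
      return(0)
    }
    sh <- sh[sh$environment == env, , drop = FALSE]
    gone <- sh$pathway_a %in% deleted & sh$pathway_b %in% deleted
    sum(sh$weight[if (deleted_only) gone else !gone])
  }
  rows <- purrr::pmap_dfr(world$strains, function(strain, deleted) {
    inv <- vapply(envs, function(e) {
      if (world$combine == "additive") {
        keep <- setdiff(world$pathways, deleted)
        world$baseline[[e]] * (1 + sum(world$weights[keep, e]) + shared_sum(e, deleted, FALSE))
      } else {
        world$baseline[[e]] * (1 - sum(world$weights[deleted, e]) - shared_sum(e, deleted, TRUE))
      }
    }, numeric(1))
    tibble(strain = strain, environment = envs, invasion = unname(inv))
  })
  wt <- rows %>%
    filter(.data$strain == "WT") %>%
    select("environment", wt_invasion = "invasion")
  rows %>%
    left_join(wt, by = "environment") %>%
    mutate(rel_invasion = .data$invasion / .data$wt_invasion) %>%
    select(-"wt_invasion")
}

# Deterministic per-record seed stream: records are numbered in a fixed
# (strain, environment, replicate) order and each draws from its own seed,
# so tables are reproducible under any generation order or subsetting.
record_seed <- function(seed, k) {
  as.integer((as.double(seed) * 100003 + 7919 * as.double(k)) %% 2147483647)
}

#' Simulate a replicate measurement table from a synthetic world
#'
#' Draws replicate invasion values around the planted means with the
#' world's noise model (default multiplicative Gaussian: `mean * (1 +
#' N(0, sd))`, truncated at zero). The output is schema-identical to the
#' measurement tables produced by image quantification, so downstream
#' modules cannot distinguish synthetic from measured input. No-growth
#' cells generate no rows.
#'
#' @param world A `synthetic_world`.
#' @param n_replicates Biological replicates per cell (default 3).
#' @return Tibble `strain`, `environment`, `replicate`, `scar_intensity`,
#'   `colony_area`, `invasion`.
#' @export
simulate_measurements <- function(world, n_replicates = 3) {
  stopifnot(inherits(world, "synthetic_world"), n_replicates >= 1)
  planted <- planted_invasion(world)
  grid <- tidyr::expand_grid(
    planted[c("strain", "environment", "invasion")],
    replicate = seq_len(n_replicates)
  )
  if (!is.null(world$no_growth)) {
    ng <- paste(world$no_growth$strain, world$no_growth$environment, sep = "\r")
    grid <- filter(grid, !paste(.data$strain, .data$environment, sep = "\r") %in% ng)
  }
  sdv <- world$replicate_noise_sd
  area <- sum(disk_mask(121, 121, c(61, 61), 60)) # nominal colony footprint
  vals <- with_preserved_seed(world$seed, {
    vapply(seq_len(nrow(grid)), function(k) {
      set.seed(record_seed(world$seed, k))
      mu <- grid$invasion[k]
      v <- if (world$noise_model == "multiplicative") {
        mu * (1 + rnorm(1, 0, sdv))
      } else {
        mu + rnorm(1, 0, sdv)
      }
      max(v, 0)
    }, numeric(1))
  })
  grid %>%
    mutate(
      invasion = vals, colony_area = area,
      scar_intensity = vals * area
    ) %>%
    select(
      "strain", "environment", "replicate",
      "scar_intensity", "colony_area", "invasion"
    )
}

#' Render a synthetic pre-/post-wash plate image pair
#'
#' The pre-wash image is a filled bright disk (the colony); the post-wash
#' image is a scar whose integrated intensity over the colony footprint,
#' divided by the footprint area, equals the planted invasion exactly
#' (before pixel noise). The scar is arranged per the planted pattern:
#' `uniform` (flat disk), `center` (Gaussian spot, sd 0.3 radius) or `ring`
#' (annulus between 0.55 and 0.9 radius). Seeded Gaussian pixel noise of
#' standard deviation `noise_sd` times the planted per-pixel mean can be
#' added to the post-wash image.
#'
#' @param world A `synthetic_world`.
#' @param strain,environment Which cell of the world to render.
#' @param image_size Side of the square image (pixels).
#' @param colony_radius Colony radius in pixels; the colony must fit.
#' @param noise_sd Pixel noise as a fraction of the planted mean signal.
#' @param bit_depth Bit depth of the rendered images (default 16).
#' @param colony_level Pre-wash disk intensity.
#' @return List with `pre_wash` (polarity `"raw"`) and `post_wash`
#'   (polarity `"inverted"`) [intensity_image()]s.
#' @export
render_synthetic_plate <- function(world, strain, environment,
                                   image_size = 192, colony_radius = 50,
                                   noise_sd = 0, bit_depth = 16,
                                   colony_level = NULL) {
  stopifnot(inherits(world, "synthetic_world"))
  maxval <- 2^bit_depth - 1
  colony_level <- colony_level %||% round(0.5 * maxval)
  if (2 * colony_radius >= image_size) abort("colony does not fit in the image")
  center <- c((image_size + 1) / 2, (image_size + 1) / 2)
  mask <- disk_mask(image_size, image_size, center, colony_radius)
  npix <- sum(mask)

  planted <- planted_invasion(world)
  hit <- planted$strain == strain & planted$environment == environment
  if (!any(hit)) abort(sprintf("no cell (%s, %s) in this world", strain, environment))
  A <- planted$invasion[hit]

  pat <- "uniform"
  if (!is.null(world$patterns)) {
    ph <- world$patterns$strain == strain & world$patterns$environment == environment
    if (any(ph)) pat <- world$patterns$pattern[which(ph)[1]]
  }

  dr <- matrix(seq_len(image_size) - center[1], image_size, image_size)
  dc <- matrix(rep(seq_len(image_size) - center[2], each = image_size),
    image_size, image_size
  )
  d <- sqrt(dr^2 + dc^2)
  post <- matrix(0, image_size, image_size)
  if (A > 0) {
    shape <- switch(pat,
      uniform = mask * 1,
      center = exp(-d^2 / (2 * (0.3 * colony_radius)^2)) * mask,
      ring = (mask & d >= 0.55 * colony_radius & d <= 0.9 * colony_radius) * 1,
      abort(sprintf("unknown pattern '%s'", pat))
    )
    # scale so that sum(post[mask]) / npix == A exactly
    post <- shape * (A * npix / sum(shape[mask]))
  }
  if (noise_sd > 0 && A > 0) {
    k <- which(world$strains$strain == strain) * length(world$environments) +
      match(environment, world$environments)
    post <- with_preserved_seed(record_seed(world$seed + 1L, k), {
      post + matrix(rnorm(image_size^2, 0, noise_sd * A), image_size, image_size)
    })
    post <- pmax(post, 0)
  }
  if (max(post) > maxval) {
    abort("planted invasion exceeds the representable intensity budget")
  }

  pre <- matrix(0, image_size, image_size)
  pre[mask] <- colony_level
  list(
    pre_wash = intensity_image(pre, bit_depth = bit_depth, polarity = "raw"),
    post_wash = intensity_image(post, bit_depth = bit_depth, polarity = "inverted")
  )
}

#' Simulate a qPCR Ct table from planted relative expression
#'
#' Inverts the 2^-delta-Ct readout: for planted relative expression `r`,
#' the target Ct is `ct_reference - log2(r)` plus Gaussian cycle noise, so
#' the noiseless table run through [summarize_qpcr()] recovers the planted
#' values exactly. By default the planted expression of gene `FLO11`
#' follows each strain's planted relative invasion and `SFG1` its square
#' root (a monotone but compressed response), in the environments named.
#'
#' @param world A `synthetic_world`.
#' @param expression Optional tibble `gene`, `strain`, `condition`,
#'   `rel_expression` (> 0) of planted expression relative to wild type.
#' @param conditions Environments used for the default expression table.
#' @param n_replicates Biological replicates (default 3).
#' @param ct_reference Reference-gene Ct (default 15 cycles).
#' @param ct_noise Gaussian noise SD in cycles (default 0.2).
#' @return Tibble `gene`, `strain`, `condition`, `replicate`, `ct_target`,
#'   `ct_reference`.
#' @export
simulate_qpcr <- function(world, expression = NULL,
                          conditions = world$environments[1:2],
                          n_replicates = 3, ct_reference = 15, ct_noise = 0.2) {
  stopifnot(inherits(world, "synthetic_world"))
  if (is.null(expression)) {
    planted <- planted_invasion(world) %>%
      filter(.data$environment %in% conditions) %>%
      mutate(rel = pmax(.data$rel_invasion, 2^-10))
    expression <- bind_rows(
      tibble(
        gene = "FLO11", strain = planted$strain,
        condition = planted$environment, rel_expression = planted$rel
      ),
      tibble(
        gene = "SFG1", strain = planted$strain,
        condition = planted$environment, rel_expression = sqrt(planted$rel)
      )
    )
  }
  if (any(expression$rel_expression <= 0)) abort("planted relative expression must be > 0")
  grid <- tidyr::expand_grid(expression, replicate = seq_len(n_replicates))
  cts <- with_preserved_seed(world$seed + 2L, {
    vapply(seq_len(nrow(grid)), function(k) {
      set.seed(record_seed(world$seed + 2L, k))
      ct_reference - log2(grid$rel_expression[k]) + rnorm(1, 0, ct_noise)
    }, numeric(1))
  })
  grid %>%
    mutate(ct_target = cts, ct_reference = ct_reference) %>%
    select("gene", "strain", "condition", "replicate", "ct_target", "ct_reference")
}

#' A default synthetic world emulating a plate-washing GEI survey
#'
#' Twelve environments and six pathways with seeded per-environment
#' contribution multipliers, combined under the deficit rule (weights are
#' fractional losses of wild-type invasion, so single deletions can drop to
#' 10-75 percent of wild type, the effect-size regime a multi-threshold
#' ranking is designed for). The defaults plant the regulatory motifs the
#' package's classifiers target: a strong-to-weak ordering of pathway
#' contributions; a conditional role reversal for each of the two weakest
#' pathways (positive in one environment, inhibitory in another); a shared
#' (redundant) contribution between two pathways in one environment with a
#' carried double-deletion strain; and an invasion-inhibiting environment
#' where no strain grows invasively (flagged no-growth and excluded from
#' ranking by convention).
#'
#' @param seed Integer seed.
#' @param replicate_noise_sd Replicate noise fraction (default 0.1).
#' @return A `synthetic_world`.
#' @export
default_gei_world <- function(seed = 1L, replicate_noise_sd = 0.1) {
  environments <- c(
    "YPD", "YP", "YPGAL", "SD", "SGAL", "SLAD",
    "SLPD", "SOE", "ME", "WL", "EtOH", "KCl"
  )
  pathways <- c("OPI1", "RIM101", "MAPK", "RAS", "RTG", "PHO85")
  # fractional loss of wild-type invasion when the pathway is deleted
  base_strength <- c(
    OPI1 = 0.55, RIM101 = 0.45, MAPK = 0.35,
    RAS = 0.25, RTG = 0.15, PHO85 = 0.15
  )
  mult <- with_preserved_seed(as.integer(seed), {
    matrix(stats::runif(length(pathways) * length(environments), 0.5, 1.5),
      length(pathways), length(environments),
      dimnames = list(pathways, environments)
    )
  })
  weights <- base_strength[pathways] * mult
  # planted conditional role reversals for the two weakest pathways: clear
  # positive and inhibitory roles in specific media, mirroring unmistakable
  # reversal phenotypes
  weights["RTG", "YPD"] <- 0.35
  weights["RTG", "SLPD"] <- -0.40
  weights["RTG", "YP"] <- 0
  weights["PHO85", "SLPD"] <- 0.35
  weights["PHO85", "SD"] <- -0.40
  # conditional redundancy: on YP the RAS and MAPK contributions are one
  # shared term; their private contributions there are small
  weights["RAS", "YP"] <- 0.05
  weights["MAPK", "YP"] <- 0.05
  shared <- tibble(
    pathway_a = "RAS", pathway_b = "MAPK", environment = "YP", weight = 0.30
  )
  doubles <- tibble(pathway_a = "RAS", pathway_b = "MAPK")
  patterns <- tibble(
    strain = c("MAPK", "RAS", "RAS", "MAPK"),
    environment = c("SGAL", "SGAL", "SOE", "SOE"),
    pattern = c("center", "ring", "center", "uniform")
  )
  strains <- c("WT", pathways, "RAS.MAPK")
  no_growth <- tibble(
    strain = strains,
    environment = "KCl"
  )
  make_world(environments, pathways, weights,
    shared = shared, double_mutants = doubles, patterns = patterns,
    baseline = 1, replicate_noise_sd = replicate_noise_sd,
    combine = "deficit", no_growth = no_growth, seed = seed
  )
}
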