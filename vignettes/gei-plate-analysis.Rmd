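---
title: "Quantifying gene-by-environment interactions in yeast invasive growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gene-by-environment interactions in yeast invasive growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geiplast)
library(dplyr)
```

## The assay and the measurement model

Budding yeast switches between round "yeast-form" growth and a filamentous,
adhesive form that penetrates agar. The plate-washing assay (PWA) reads this
out: a colony is grown on solid medium, surface cells are washed away, and
the cells that invaded the agar remain as a visible *invasive scar*. The
darker and larger the scar, the more invasion occurred.

`geiplast` turns scar photographs into numbers with a deliberately simple
measurement model:

1. **Background removal.** The local background of the washed-plate image is
   estimated by a grayscale morphological opening with a disc structuring
   element (the rolling-ball idea: any feature narrower than the disc is
   background-subtracted away) and subtracted. The disc radius must exceed
   the scar scale; the default of 50 px suits typical plate images where
   scars span 100-300 px. After subtraction the image carries *inverted*
   polarity: higher value = more invasion signal.
2. **Contrast rescaling.** Intensities are mapped linearly so that chosen
   percentiles (defaults: 1st and 99th) hit 0 and the bit-depth maximum.
   Crucially, `preprocess_scar_batch()` computes the percentiles from the
   *pooled* pixels of the whole batch and applies one shared linear map.
   Rescaling each image by its own percentiles would equalize images that
   differ only in scale and destroy exactly the between-strain ratios the
   analysis is built on; a single shared map is also the faithful reading of
   the equal-treatment rule that every image of an experiment receives the
   same adjustment parameters.
3. **Colony outline.** The colony footprint on the *pre-wash* image is
   thresholded (Otsu by default), the connected component nearest a
   user-supplied hint is selected, and its equivalent circle (centroid
   center, radius $\sqrt{n/\pi}$) becomes the measurement region - the
   automated stand-in for a hand-drawn circular outline. A manual
   `(center, radius)` override reproduces hand-drawn circles exactly.
4. **Invasion index.** The circle is placed over the registered post-wash
   image and

   $$\mathrm{invasion} = \frac{\sum_{\text{pixels in circle}} I}{\text{area}}$$

   i.e. integrated inverted scar intensity divided by colony area, which
   controls for growth differences between strains.
5. **Relative invasion.** Per environment, each strain's replicate-mean
   invasion is divided by the wild-type replicate mean, so wild type is
   exactly 1. Replicate SD is propagated on the same normalized scale.
   No-growth cells are flagged from metadata, never imputed: the image of a
   washed plate cannot distinguish "did not grow" from "grew but did not
   invade".

Pre- and post-wash images are assumed pixel-registered (same plate, same
imager); a translation offset argument covers small rigid shifts. There is
no grid detection or barcode reading - hints come from a layout table.

### Coordinates and geometry

All coordinates are 1-based `(row, col)` with a top-left origin, the native
R convention. Regions are *closed disks* on the pixel grid: a pixel belongs
to the disk when its center lies within the radius. Every geometric
quantity in the package (segmentation areas, invasion sums, synthetic
renders, well crops) uses this one membership rule, which is why zero-noise
round trips recover planted values to machine precision rather than "within
a pixel or two".

## Plot profiles and microenvironment patterns

Invasion is not spatially uniform: depending on the environment, mutants
may lose invasion specifically in the scar center or in a surrounding ring.
To quantify this, a square crop is taken around the scar and a band of
40 px height is drawn across its midsection, edge to edge; the profile is
the per-column mean grey value along the band. Profiles are taken along
three axes - 0, 60 and 120 degrees through the scar center, a choice made
here since the original three-axis procedure does not specify them - and
averaged element-wise. Axis-aligned angles are computed exactly as column
means; other angles rotate the sampling frame with bilinear interpolation,
clamping sample coordinates to the crop (replicating edge pixels), so a
constant image yields a constant profile at every angle.

The qualitative center/ring reading is formalized in
`classify_invasion_pattern()`: after converting to invasion-positive
polarity the transect is split into a center third and two outer thirds;
`center_ratio` (center-third mean over overall mean) and `ring_ratio`
(outer-thirds mean over overall mean) are compared against a cut of 1.25.
The cut is a package-invented, configuration-exposed constant - the
original pattern reading was qualitative - chosen so that a 25 percent
enrichment is called and anything flatter is `uniform`; profiles matching
neither rule are `diffuse`.

## Adhesion particle statistics

Cell adhesion assays (liquid-culture clusters, within-colony adhesive
particles, crystal-violet-stained plastic wells) are quantified with the
binary-image "analyze particles" idiom: one fixed per-assay threshold
(equal treatment again), connected-component labeling, and particle counts
and areas. Connectivity defaults to 8 (edge plus corner neighbors, the
ImageJ convention) and is selectable; components below `min_size = 4` px²
are discarded to suppress single-pixel noise (the threshold is a package
default; no value was prescribed). Mean cluster area is the metric for
liquid cultures, total particle area for colony and plastic adhesion; both
normalize to wild type = 1.

## Ranking regulators across environments

For each mutant the package computes, across the included environments
(no-growth environments excluded), the mean relative invasion with its
sample SD, and the number of environments in which the mutant fell to or
below each threshold of the ladder $\{0.75, 0.50, 0.25, 0.20, 0.15,
0.10\}$ of wild-type invasion. Comparison is inclusive (`<=`), so the
counts are non-increasing down the ladder. Because "rank using all
thresholds" admits several orderings, the rank of record is the
**composite score** - the sum of the six counts - with ties broken by
ascending mean relative invasion and then label order. The composite
reproduces any lexicographic order whenever the counts are nested (which
the ladder guarantees) and is stable under small perturbations; both
summaries (mean and counts) are reported side by side.

## The statistics layer

Group comparisons follow the standard plate-assay design: one-way ANOVA,
Dunnett's multiple-comparison test for mutants versus wild type, Tukey's
HSD for mutant-versus-mutant comparisons, 95 percent confidence intervals,
and adjusted p-values. Both procedures use the single-step multivariate-t
implementation in **multcomp**. Two numerical choices matter:

* the multivariate-t probabilities are evaluated by randomized
  quasi-Monte-Carlo; the package runs them under a fixed internal seed
  (restoring the caller's RNG state) so that repeated runs produce
  identical output files;
* adjusted p-values are clamped to be at least the raw p-values - true
  mathematically for single-step procedures, and the clamp removes the
  Monte-Carlo jitter that could otherwise violate it in the 15th decimal.

Student's t is pooled-variance by default (Welch selectable), as the
plate-assay replicate design gives no reason to expect unequal variances.
qPCR expression uses the $2^{-\Delta C_t}$ formula against the ACT1
reference; biological replicates are averaged in $\Delta C_t$ space before
exponentiation, because cycle space is where the measurement error is
symmetric. Morphometry reports the length-to-width ratio as max/min (so
orientation cannot flip it below 1) and the distal-bud percentage; the
stated minima (25 cells, 100 buds) are warnings, not errors.

## Interaction classifiers

The classifiers formalize qualitative genetic reasoning as explicit
decision rules on replicate sets:

* **Role calls**: a mutant significantly below wild type (two-sided test at
  `alpha`) marks the pathway as a positive regulator in that environment;
  significantly above, negative; otherwise none. Batched calls use Dunnett
  versus wild type per environment.
* **Role reversal**: at least one environment with a positive role and one
  with a negative role; the witnesses are reported.
* **Double mutants**: all four groups (wild type, singles, double) enter a
  Tukey-adjusted comparison. `additive` means the double is significantly
  below both singles; `redundant_to_a` that it is indistinguishable from
  single *a* and below single *b*; `redundant_to_both` indistinguishable
  from both; anything else - including a double above a single - is
  `indeterminate`.
* **Sensing**: applicable only when wild type itself differs significantly
  between two environments; a mutant with no significant change is a
  sensing candidate, a mutant that still changes is non-sensing. A mutant
  changing significantly in the *opposite* direction is classified
  non-sensing: it still discriminates the environments.

"Indistinguishable" is failure to reject equality - an
absence-of-evidence rule, flagged as such in the output (`rule` column).
For stricter claims an equivalence mode runs TOST (two one-sided tests) at
a margin expressed as a fraction of the wild-type mean (default 0.25); the
margin is a scientific choice the caller must own, which is why the
default mode remains the transparent non-significance rule.

## The synthetic-data generator

Every downstream module is validated against `make_world()`, a generative
model with planted ground truth: environments, pathways, a signed
pathway-by-environment contribution matrix (negative entries plant
inhibitory roles and hence role reversals), shared contributions attached
to pathway pairs (deleting one member leaves the term; deleting both
removes it - the simplest model of redundancy consistent with observed
single/double-mutant patterns), per-cell scar patterns, per-environment
baselines, a replicate noise level, and a seed.

Two combination rules are available, and the distinction is a real modeling
point rather than a convenience:

* **additive** (default): wild-type invasion is
  $b_e\,(1 + \sum_p w_{pe} + \sum s)$ and a deletion subtracts its terms.
  Under this rule the fractional loss caused by deleting pathway $p$ is
  $w_{pe}/(1+\sum w)$, and these fractions *must* sum to less than 1 across
  pathways. Many simultaneously strong regulators are therefore impossible
  by construction - with six pathways the average deletion can cost at most
  one sixth of wild-type invasion.
* **deficit**: weights are fractional losses directly; a strain with
  deleted set $D$ has invasion $b_e\,(1-\sum_{p \in D} w_{pe} - \text{shared
  terms inside } D)$. This is the regime real surveys show - single
  deletions dropping to 10-75 percent of wild type across many pathways at
  once (epistatically, not by partitioning a fixed budget) - and it is the
  rule used by `default_gei_world()` and by the ranking-recovery
  validation, where six planted mean relative invasions separated by 0.15
  are required.

Replicate noise is multiplicative Gaussian, truncated at zero
(`mean * (1 + N(0, sd))`, default sd 0.1), because plate-assay spread
scales with signal; additive noise is selectable. Random draws use a
counter-based stream: each record of the (strain, environment, replicate)
grid draws from its own seed derived from the world seed and the record
index, so tables are bit-reproducible regardless of generation order or
subsetting, and changing only the seed changes values but never schema or
planted means.

`render_synthetic_plate()` produces image pairs whose integrated post-wash
intensity over the colony footprint, divided by footprint area, equals the
planted invasion *exactly* before pixel noise, with the scar arranged
uniformly, as a center Gaussian (sd 0.3 radius), or as an annulus (0.55 to
0.9 radius - kept inside the colony footprint so segmentation-boundary
jitter cannot clip it). `simulate_qpcr()` inverts the $2^{-\Delta C_t}$
readout so the noiseless table round-trips exactly.

What the generator does *not* emulate: uneven illumination and plate-edge
vignetting, colony morphology (ruffling), spatially correlated noise,
scar-shape irregularity, or growth differences between strains (synthetic
colonies share one footprint). Passing the validation suite therefore
demonstrates that the pipeline's arithmetic, geometry, statistics and
decision rules are correct under the stated model - not that segmentation
is robust to arbitrary real-plate artifacts.

## Validation conditions and problem sizes

The package's own validation (the acceptance suite and
`scripts/acceptance.R`) uses these problem sizes, chosen as the smallest
that make the statistical claims meaningful: 100 seeded random instances
per brute-force-oracle comparison; 160-px plates with 50-px colonies and
90-px profile crops; 200 seeded simulations for pattern recovery at 20
percent pixel noise and for ranking recovery at 10 percent replicate noise
with three replicates and eleven environments; 1000 null simulations for
the family-wise-error and signed-call-rate checks (reported with
two-Monte-Carlo-SE slack). "Zero noise" for the classifier grid is
operationalized as 0.5 percent replicate noise, because the significance
rules the classifiers are built on are undefined at literally zero
variance.

## Known limitations

* Registration between pre- and post-wash images is assumed; only a global
  translation offset is exposed.
* Background subtraction is global (one opening per image); there is no
  per-lane or per-well local background model.
* The redundancy calls inherit the weaknesses of non-significance reasoning
  at small n; use the TOST mode when claiming equivalence matters.
* The pattern classifier reads one averaged transect; it does not compute
  2-D radial maps and can mislabel strongly asymmetric scars as `diffuse`.
* Time courses are handled as independent per-time-point matrices; there is
  no longitudinal model.
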