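---
title: "Similarity-based distribution and coverage mapping with casemap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity-based distribution and coverage mapping with casemap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casemap)
```

## The problem and the approach

`casemap` maps the distribution and ground coverage of a patchily
distributed species — the motivating system is a clonal shrub of thin-soiled
limestone (alvar) grasslands — over a large area from point field records
and categorical site rasters (land cover, soil). Instead of fitting a
statistical niche model, it reasons by cases: a site is expected to carry
the species at a coverage similar to that of the observed *exemplar* sites
it most resembles. The model object is therefore not a coefficient vector
but a weighted case base: a set of exemplar sites, a weight per site
feature, a weight per exemplar, and a similarity budget that controls how
much evidence is gathered before a decision is made. All of these are
machine-learned against a validation objective.

## The similarity metric

Similarity between an observation $O$ and an exemplar $E$ is a weighted
variant of Gower's coefficient for mixed feature types. For a numeric
feature $f$ with training-data standard deviation $SD_f$, the partial
similarity is

$$PS(O_f, E_f) = w_f\, w_e \left(1 - \frac{|F_e - F_o|}{k\, SD_f\, w_f\, w_e}\right),$$

clamped at zero, where $w_f$ is the feature weight, $w_e$ the exemplar
weight and $k$ the similarity budget. Equivalently
$PS = \max(0,\; w_f w_e - |F_e - F_o| / (k\, SD_f))$: the weight product
acts as a similarity cap, and a feature with a larger weight tolerates a
wider value difference before its contribution hits zero. For a categorical
feature, matching categories score one and differing categories zero,
scaled by the same weights ($PS = S_c\, w_f\, w_e$). The type system keeps
room for user-supplied category-to-category similarity tables, but only the
0/1 indicator is implemented.

Total similarity is the weight-normalised mean

$$TS(O, E) = \frac{\sum_f PS(O_f, E_f)}{\sum_f w_f\, w_e} \in [0, 1],$$

where both sums run only over features that are positively weighted and
non-missing *on both sides*. Missing data therefore reduces the evidence
base instead of blocking the comparison; a pair with no usable shared
feature is flagged (a typed condition) rather than silently scored 0.
Zeroing a feature's weight is exactly equivalent to deleting the feature.

**Inference.** For each target site, exemplars are ranked by $TS$
(descending, ties broken by exemplar id so results are seed-independent)
and accumulated until the summed similarity reaches the budget $k$; the
exemplar crossing the threshold is included in full (fractional inclusion
would complicate the certainty bookkeeping for little gain; the choice is
flagged for sensitivity testing). Exemplars with zero or undefined
similarity carry no evidence and are never included; if the base is
exhausted before reaching $k$ the set is flagged. A coverage prediction is
the $TS$-weighted mean of the set's coverages — the natural analogue of
weighted nearest-neighbour regression, consistent with "similar sites carry
similar coverage". A presence/absence prediction is the class holding the
larger accumulated similarity, with *certainty* defined as that class's
similarity share: 1 for a single-class decision set, near 0.5 for a
near-tie. An exact tie goes to absence — for a protected species a false
absence is the costlier mapping error, so the conservative call is
deliberate. The mean $TS$ of the set is reported alongside as a
reliability measure: low values flag a lack of similar exemplars and hence
a data gap, not merely an uncertain decision.

## Learning the weight state

The tunable state — feature weights, exemplar weights, budget $k$ — is
fitted by stochastic hill-climbing (`simfit()` / `learn_weights()`). Each
iteration:

1. draws fresh training and validation subsamples without replacement
   (defaults 500 and 1000, capped at the data size with a warning);
2. evaluates the current state and one proposed perturbation on that draw:
   multiply one feature weight, one exemplar-weight block, or $k$ by a step
   factor from {0.5, 0.8, 1.25, 2}, or zero out the exemplar contributing
   the least similarity across the draw's decision sets;
3. accepts the proposal if it improves the validation objective — the True
   Skill Statistic (sensitivity + specificity − 1) for presence/absence,
   RMSE on the 0–1 coverage scale for coverage.

Class proportions are never rebalanced in the samples. A validation record
that also sits in the iteration's exemplar base is excluded from its own
decision set, so self-matching can never flatter the objective. Exemplar
weights are perturbed in blocks (the two classes, or coverage strata cut at
0, 0.3 and 0.6) because individually searchable weights for thousands of
records would be hopeless within a few hundred iterations; individual
exemplars can still be removed one at a time by the zeroing move. The state
with the best validation objective seen is returned, and the per-iteration
trace (with its monotone best-so-far envelope) is kept on the object for
`plot()`.

**Ties.** Acceptance on strict improvement alone turns out to freeze the
search as soon as the objective saturates (TSS = 1 is reached quickly when
a feature separates the classes perfectly), leaving redundant noise
features and exemplars untouched. An exact objective tie is therefore
accepted under a secondary criterion: first a larger class-separation
margin — the mean, over validation records, of the whole-base similarity
share belonging to the record's true class (the "similarity to a given
category" quantity; unlike decision-set certainty it does not saturate once
decision sets are pure) — then, on margin ties, non-increasing complexity
(summed feature weights plus active exemplar count). Budget moves always
require strict improvement: a different $k$ is not a simpler model, just a
differently smoothed one. The net effect is that on a plateau informative
weights grow, uninformative weights shrink toward zero and redundant
exemplars are pruned, while the objective never worsens.

One master seed drives every draw; reruns are bit-identical and the
caller's RNG stream is left untouched.

## Site features

Beyond raster lookups (land cover, soil, and their 200 m modal smoothing
via `modal_category()`), the strongest predictors in this setting are
spatial autocovariates of the species' own records: the proportion of
presences and the mean coverage within 100 and 1000 m, and an
inverse-distance-weighted mean coverage within 10 km (`idw_mean_coverage()`,
power 1 by default — no exponent is better motivated, and 1 is the least
aggressive choice; distances are floored at half a 10 m cell so a record at
the evaluation point cannot dominate). All neighbourhood statistics return
missing (not zero) for empty neighbourhoods, so similarity computation
skips them — an unsampled neighbourhood is unknown, not unoccupied. When
these features are evaluated *at* a record's own location the focal record
is excluded from its neighbourhood; otherwise the feature would leak each
record's own coverage into its predictors.

Records are first thinned to a minimum spacing (50 m by default) to level
out the very uneven density of walked-track observations. Presences are
processed before track-derived absences — a presence is never sacrificed to
keep a nearby track point, which is the reading consistent with treating
track points more than 50 m from any presence as absences — and the greedy
pass follows input order within each class. Thinned sets are fixed points
of the operation.

## Spatial partitioning

The output grid (100 m interval by default) is pre-classified before any
learning:

* **proved absence** — cells of a land-cover-by-soil stratum that holds
  more than 1% of all records without a single presence. The stratum is the
  counting unit (the area-share reading would let a few records condemn a
  large rare habitat); the 1% threshold means rare strata can never prove
  absence, however many absences they contain.
* **probable presence** — cells where at least two of the four most firm
  presence predictors fire. These predictors come from an upstream feature
  screening and are configuration, not something this package learns; the
  defaults (`default_partition_rules()`) use the autocovariate features.
  Probable presence overrides proved absence where both rules fire.
* **unclear** — everything else; typically most of the area.

Each partition gets its own learning pool (`route_records()`; the pools
partition the record set exactly) and its own predictive set: coverage is
learned directly in the probable-presence partition; the unclear partition
gets a presence/absence set first and a coverage set for its
predicted-presence cells, absence-predicted cells scoring coverage 0.
Proved-absence cells are fixed at coverage 0 by definition and no decision
is computed there. Certainty is reported only where a class decision was
made (the unclear partition); the mean-similarity layer reports the
decision that produced each cell's final coverage value. Missing decisions
(no usable similarity) propagate as NODATA — never silently coerced to
zero, except in proved absence where zero *is* the definition. Finally the
observed records overwrite their cells (mean coverage per cell when several
records share one — the unbiased choice for a fraction), field data being
more reliable than any calculation.

## Synthetic study systems

Because the real inputs (licensed national land-cover and soil layers,
field campaigns) cannot ship with a package, `casemap` includes a
first-class generator whose defaults describe a study system with the same
statistical structure: categorical mosaics grown by region-growing from
random seeds (region-growing rather than Gaussian random fields: simpler,
dependency-free, and patch mosaics are what categorical land cover looks
like); clonal presence patches seeded preferentially in favoured land-cover
categories (20:1 by default; `Inf` makes favouring exclusive); survey-point
coverages drawn zero-inflated — a 0.6 point mass at zero with a right-
skewed beta tail scaled to 0.9, matching a zero-dominated coverage
histogram whose maximum observed coverage is 0.9; and walking tracks
simulated as correlated random walks with ~12 m steps, giving the densely
oversampled point chains that make thinning meaningful. Default extent is
100 × 100 cells of 10 m. Ground truth (patch centres, the occupied-cell
mask, the generating configuration) is always returned, so recovery tests
compare against known quantities.

What the generator deliberately does not emulate: the real landscape's
category frequencies and record counts, geodesy (all coordinates are planar
metres), observer error in visual coverage estimation, and temporal change
across field seasons. Passing tests therefore demonstrate the machinery —
metric correctness, retrieval, learning recovery, determinism, partition
semantics — not field-data predictive skill.

## Numerical and design choices

* Numeric feature SDs are computed once from the training data and frozen
  into the model; prediction-time data never changes them (no leakage, no
  drift).
* Ranking ties (equal $TS$) break by exemplar id; class ties resolve to
  absence with certainty 0.5. Modal-category ties take the smallest code.
* Grid cells follow a half-open convention: a point on a shared edge
  belongs to the cell to its south-east. Rasters are ESRI ASCII grids
  (plain text, NODATA-preserving round trips).
* The similarity kernel is compiled (Rcpp): the matrix form
  $PS = \max(0, w_f w_e - |d|/(k\,SD))$ over observation-by-exemplar blocks,
  and budget retrieval by incremental partial selection rather than a full
  sort, since decision sets are usually far smaller than the base.
* Problem sizes in the shipped tests: learning recovery uses n = 2000
  records, 200 iterations, 10 seeds; the pipeline checks run on a
  100 × 100-cell landscape with a 10 × 10 output grid. These sizes keep the
  whole suite in a few minutes while leaving every mechanism exercised at
  the study's learning parameters (samples of 500/1000, initial k = 5,
  200 iterations).

## A small worked run

```{r example, eval = FALSE}
cfg <- synth_config(seed = 11)
landscape <- generate_landscape(cfg)
obs <- generate_observations(landscape, cfg)
run <- run_mapping(obs$records, landscape,
                   control = simfit_control(seed = 12))
run$report
summary(run$fits$probable_presence)
write_ascii_grid(run$coverage_final, "coverage.asc")
```

## Known limitations

* Autocovariate features are only informative near existing records; far
  from any record they are missing and the prediction falls back on the
  categorical layers alone, with correspondingly lower mean similarity.
* The hill-climbing search is local; with few iterations it can keep an
  uninformative feature at a non-zero weight. The trace and the retained
  exemplar count on the fitted object are the diagnostics to inspect.
* Partition rules are configuration. With small record sets the 1% stratum
  rule is aggressive (a handful of absences can prove a stratum absent);
  at study scale (thousands of records) it behaves as intended.
* Category-specific similarity tables and the upstream boosted-tree feature
  screening are out of scope; predictors for the probable-presence rule
  must be supplied.
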