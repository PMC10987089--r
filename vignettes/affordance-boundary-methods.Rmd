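---
title: "Methods: locating an affordance boundary from object-action judgments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locating an affordance boundary from object-action judgments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affbound)
```

## The scientific question

An object's affordances — what you can do with it — depend on your body.
Things smaller than you attract hand-scale actions (grasping, holding,
throwing); things larger than you attract whole-body actions (sitting,
standing, entering). If perceived affordances really are organized around
the body, the similarity between the affordance profiles of objects should
not decay smoothly with object size: it should collapse abruptly at a
*boundary* near the agent's own body size, and that boundary should move
when the (imagined) body size moves.

`affbound` implements the full analysis chain for testing this idea on
binary object-action judgment data, plus a synthetic generator so that every
stage can be validated against data whose ground truth is known.

## Data model

The raw input is a complete binary tensor: `n` participants × 14 actions ×
`K` objects, each cell a yes/no judgment of whether the object affords the
action. Each object carries its real-world bounding-box diagonal (cm), an
animate flag, and a *size rank* — an integer category of the diagonal on a
logarithmic scale (ranks 2–8 here). Animate objects are excluded before
analysis (their affordances are not comparable with those of inanimate
things); coverage must be complete, and any missing cell is an error rather
than an implicit "no".

### Size-rank bins

The rank scale is logarithmic but its bin edges are not published anywhere
we can consume; what is certified are anchor pairs of mean size and rank
(17 cm → rank 2, 77 → 4, 146 → 5, 577 → 7, 5317 → 8). The default edges in
`default_rank_edges()` therefore pass *through* the printed per-rank mean
sizes where available (77, 146, 577 cm) and interpolate on the log scale
elsewhere (38, 290, 1752 cm), bounded by 9.5 and 16000 cm. Bins are
half-open, `[lower, upper)`, so a size exactly on an edge belongs to the
higher rank; this makes the map reproduce all five anchors exactly and
keeps it monotone. Edges are configurable in `analysis_config()` for data
sets with their own rank definitions.

## Pipeline

1. **Affordance vectors** (`affordance_vectors`): per object, the fraction
   of participants endorsing each action — a 14-dimensional profile.
2. **Representational similarity matrix** (`similarity_matrix`): Pearson
   correlation between every pair of affordance vectors. A zero-variance
   vector has no defined correlation; its cells are masked (`NA`), never
   silently zeroed.
3. **Clustering** (`cluster_similarity`): agglomerative clustering of the
   RSM's rows (each object's similarity profile) under Euclidean distance
   and complete linkage, cut at k = 2. We cluster similarity profiles
   rather than raw affordance vectors because the claim under test is about
   the structure of the similarity matrix itself; `stats::hclust` breaks
   merge ties deterministically given the input order.
4. **Rank curve** (`rank_mean_vectors`, `neighbor_similarity_curve`):
   affordance vectors are averaged (unweighted) within each size rank, and
   `r[i]` is the correlation between the mean vectors of ranks `i` and
   `i+1`. The per-point standard error is `sqrt((1 - r^2) / (n - 2))` with
   `n = 14` actions (the Fisher-z alternative `1 / sqrt(n - 3)` is used for
   the Bayes-factor standard error, below).
5. **Trough statistic** (`trough_value`, `detect_trough`,
   `permutation_test_trough`): the trough value at site `i` is
   `(r[i-1] + r[i+1]) / 2 - r[i]` — how far the curve dips below the mean
   of its two banks. The site is either fixed a priori in the config or
   detected as the interior maximizer (ties to the smaller rank; both modes
   exist because it is genuinely ambiguous which one a confirmatory analysis
   should use, and the choice belongs to the analyst). Significance comes
   from a permutation test.
6. **Pairwise comparisons** (`compare_neighbor_correlations`): neighboring
   curve points share a rank, so they are dependent overlapping
   correlations. We use Steiger's (1980) Z with the mean-correlation
   modification (the `cocor` package's "steiger1980" variant), one-tailed,
   with Zou's (2007) interval as an alternative view.
7. **Object-level scan** (`pairwise_boundary_scan`): all object pairs from
   the same or adjacent ranks within a window (default ranks 3–6) are
   traversed; each pair contributes its affordance correlation and mean
   size. The boundary estimate is the mean pair size of the rank
   composition with the lowest mean similarity.
8. **Size-similarity control** (`size_similarity`): `1 - (d_j - d_i)/d_i`
   between neighboring ranks' mean sizes — deliberately asymmetric, with
   the smaller rank as reference. Because physical size changes smoothly
   across ranks, this control curve has no trough where the affordance
   curve does; the pipeline reports both so the contrast is explicit.

## Permutation test design

The permutation null asks: would a trough this deep at this site arise if
object size carried no information about affordances? Each permutation
shuffles the object-to-rank assignment, preserving the per-rank object
counts, then recomputes the rank curve and evaluates the trough value at
the *same* site. The p-value is the plain exceedance fraction
`p = (1/N) * #(T_i >= T_obs)`, which can legitimately return 0; the
`(count + 1) / (N + 1)` estimator is available behind
`analysis_config(p_smoothing = TRUE)` for users who prefer a positively
biased but never-zero estimate. An alternative exchange unit —
independently shuffling each object's affordance vector across actions —
is available via `permute = "actions"`; note that jointly permuting the
action axis would leave every Pearson correlation unchanged and is
therefore not a usable null. Default `N` is 5000.

With the site fixed a priori, the permutation p is calibrated: under a
boundary-free generator its distribution is approximately uniform and the
rejection rate at α = 0.05 stays near 0.05 (the test suite checks both
over 200 simulations). Detecting the site first and then testing it on the
same data is a post-hoc analysis and inflates the rejection rate; the
report records which mode produced its site.

## Bayes factors

The evidence comparison for "these two neighboring similarities differ"
follows a normal-normal construction on the Fisher-z scale: the observed
effect is `z_obs = atanh(r_a) - atanh(r_b)` with standard error
`1 / sqrt(n - 3)`, the null hypothesis is a standard normal prior centered
at 0, and the alternative a normal centered at 2. Both marginal likelihoods
are then normal and BF10 is available in closed form. The alternative's SD
is not recoverable from the construction we emulate; the default of 1
(matching the null's spread) is an explicit assumption, configurable via
`h1_prior_mean` / `h1_prior_sd`, and BF values should be read with that in
mind. BF10 > 10 is reported as strong evidence by convention.

## The synthetic generator

`simulate_judgments()` draws independent Bernoulli responses under a
logistic boundary model: for object diagonal `d`, agent size `B` and action
class `s` (−1 manipulation, +1 whole-body),

```
p = lapse/2 + (1 - lapse) * gain * plogis(s * beta * log2(d / B))
```

Defaults emulate the study conditions the package targets: 528 participants,
24 inanimate objects over ranks 2–8 (per-rank counts 3, 4, 4, 4, 4, 3, 2,
concentrated at mid ranks like the emulated stimulus set, sizes log-uniform
within each rank bin), 14 actions split 7/7 between the classes,
`agent_size_cm = 150` (adult human diagonal; 77 emulates a cat-sized body,
577 an elephant-sized one), `beta = 4` (a size ratio of 2 moves the
endorsement probability to `plogis(4) ≈ 0.98` of its range), `lapse = 0.05`,
unit action gains. Optional per-action gains and a per-participant logit
offset (`participant_sd`) de-idealize the data.

What the generator emulates: the two-sided switch of endorsement around a
latent body-size boundary, binomial sampling noise, lapses, and the rank
structure of the stimulus set. What it does not emulate: action semantics
beyond a binary class (real "grasp" and "throw" profiles differ), item
effects, response styles, order effects, or participant-level body-size
variation. Consequently, with unit gains the generated rank curve is nearly
±1 outside and at the trough — an idealized, sharper version of the
empirical pattern (real within-side similarities are high but far from 1).
Passing recovery tests on this data shows the *statistics* behave as
designed; it does not certify performance on messier empirical profiles.

## Numerical and design choices

* Correlations of constant vectors are undefined: masked with a warning,
  propagated as `NA`, and excluded from clustering — never imputed.
* `trough_value` is exact arithmetic on the curve; it is linear under
  scaling of the curve and invariant under constant shifts (tested).
* Trough-site ties break toward the smaller rank; clustering ties follow
  `stats::hclust`'s deterministic rule.
* The boundary-location CI is a seeded percentile bootstrap (1000
  resamples) over the pairs of the minimum-similarity composition;
  per-composition normal-approximation CIs are also reported and masked
  for singleton compositions.
* Every random step (generation, permutation, bootstrap) flows from an
  integer seed recorded in the config and echoed in the report, so reruns
  are bit-identical.
* Problem sizes used by the validation suite: 200 simulated participants
  for recovery runs, 1000 permutations for the headline test, 200
  simulations × 500 permutations for null calibration, 2000 simulations
  for kernel calibration — sizes at which the checked binomial and KS
  tolerances are sharp.

## Known limitations

* The boundary estimate is resolved only to the granularity of the rank
  compositions; with few objects per rank its CI is wide.
* Steiger's Z and the Fisher-z standard errors are asymptotic in the number
  of actions (here 14); they are adequate for calibration (tested by
  simulation) but not exact at this dimension.
* The Bayes factor depends on an assumed prior SD under H1 (see above).
* With `k = 2` clusters and objects that straddle the boundary mid-rank,
  cluster membership follows each object's own size, not its rank — the
  partition can split a rank.

## A minimal run

```{r example, eval = FALSE}
cfg <- analysis_config(n_permutations = 1000, seed = 42)
gen <- generator_config(n_participants = 200, agent_size_cm = 150, seed = 42)
tensor <- simulate_judgments(gen, cfg)
report <- run_analysis(tensor, cfg)
print(report)
write_report(report, "affbound_out")
```
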