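---
title: "Seasonal niche models and migration analytics: methods"
author: "migrasdm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seasonal niche models and migration analytics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migrasdm)
```

## The modelling problem

GPS collars on migratory caribou record a fix every 8 hours — 1095
relocations per animal in a non-leap year — but they only record where
animals *were*, never where they were not. `migrasdm` implements the
presence/pseudo-absence workflow that turns such telemetry, together with a
stack of co-registered 500-m environmental rasters, into seasonal
distribution models and migration summaries:

1. **Seasonal presence sets.** Fixes are split into six seasons that
   partition the year: spring (Apr 1–May 27), calving (May 28–Jun 14),
   insect relief (Jun 15–Jul 14), late summer (Jul 15–Aug 31), fall
   (Sep 1–Nov 30) and winter (Dec 1–Mar 31). Winter wraps the calendar
   year; its fixes carry the year of the December that started it, so each
   winter is contiguous.
2. **Density-matched pseudo-absences.** Because absences are not observed,
   random background cells stand in for them. Their count is
   `n_presences × study_area / hull_area`, where `hull_area` is the area of
   the minimum convex polygon around the season's presences. This keeps the
   *density* of background points equal to the density of presences, so
   seasons whose range is compact are not swamped by background. The count
   is rounded to the nearest integer (unbiased; the rule is silent on
   rounding) and, on frames too small to supply that many presence-free
   cells, capped at the number available with a warning. Pseudo-absences
   are never placed in a cell holding a presence fix of the same model, so
   no training cell carries both labels.
3. **Boosted trees.** A stochastic gradient-boosted ensemble of small
   decision trees with binomial loss classifies presence vs.
   pseudo-absence. The learner is xgboost configured to the classical
   boosting contract: `n_trees` sequential trees (default 1000), at most
   `max_nodes` leaves per tree (default 6), at least `min_cases` cases per
   terminal node (default 10), learning rate 0.01, and random 50% row
   subsampling per tree. With `class_balance = TRUE` (default) the presence
   class is reweighted by the class ratio so unequal class sizes contribute
   equally to the loss. Fits are single-threaded with a derived seed, so
   every run is reproducible bit-for-bit.
4. **Scoring, smoothing, thresholding.** The fitted model is scored to
   every unmasked cell centre; inverse-distance weighting (power 2, 12
   neighbours, exact at nodes) smooths point scores into a continuous
   relative index of occurrence (RIO) in [0, 1]. The RIO surface becomes a
   binary presence map at the *balanced threshold*: the candidate cutoff
   (midpoints of consecutive sorted unique scores, plus 0 and 1) that
   minimises false positives + false negatives, with ties broken first by
   the smallest |sensitivity − specificity| and then by the lower
   threshold. Predictions at exactly the threshold count as presence.
5. **Migration analytics.** Annual spring/fall maps yield predicted areas
   (presence pixels × 0.25 km² at 500-m cells), composite frequency maps
   (per-pixel count of years predicted present), repeated-use corridors
   (≥ `min_years`, default 5), and deviations of each year's mean observed
   position from the pooled mean.
6. **Land-cover selection.** Predicted presence is cross-tabulated against
   a categorical land-cover map; the selection index for a class is its
   share of predicted use divided by its share of availability. Values
   above 1 indicate selection. The land-cover layer is deliberately *not* a
   model predictor — `run_seasonal_model()` refuses stacks containing it
   unless overridden — because using it as a covariate would make the
   post-hoc selection ratios circular.

## Conventions that matter

* **Pixel area.** Cells are 500 m × 500 m, i.e. 0.25 km² per pixel. Four
  presence pixels make 1 km².
* **Degrees to kilometres.** Positional deviations use a fixed
  111.5 km/degree on *both* axes, without a cosine correction for
  longitude. This is the reporting convention of the study region's
  published tables, which this package reproduces exactly; a
  cosine-corrected mode (`cosine_correct = TRUE`) is available but off by
  default. Longitude deviations are west-positive and rendered with E/W
  letters; latitude north-positive with N/S.
* **Grid indexing.** Cells are 1-based, row-major with row 1 at the bottom;
  a point exactly on an interior cell boundary belongs to the cell to its
  lower-left. Extraction is nearest-cell (no interpolation), which keeps
  categorical layers safe and matches the point-on-grid scoring design.
* **Model grading.** Overall accuracy ≥ 0.90 is "excellent", ≥ 0.80
  "good", ≥ 0.70 "fair", else "poor". The published wording leaves exact
  boundaries open; boundaries here map to the higher grade.
* **Holdout.** 20% of the training table, stratified by label, is withheld
  before fitting and used for the reported AUC/accuracy. The balanced
  threshold is computed on the full training table; the published
  procedure does not say which rows it used, and the full table is the
  larger, more stable choice.
* **Partial dependence.** Friedman partial dependence on the latent
  log-odds scale: each grid value is forced into every training row, latent
  predictions are averaged, and the curve is centred to mean zero. Positive
  stretches of the centred curve are the association ranges reported by
  `extract_association_ranges()`; the lower endpoint of the first positive
  interval estimates a threshold response.
* **Seeds.** A single root seed per run; every stage (landscape, telemetry,
  pseudo-absences, split, boosting) derives its own child seed by stable
  string hashing, so stages are independently reproducible and reordering
  one does not perturb another.

## What the synthetic generator emulates — and what it does not

Real telemetry and rasters for the study system are archived restricted
data, so the package carries a generator with known ground truth:

* Continuous predictors are Gaussian random fields — white noise smoothed
  with a Gaussian kernel of width `correlation_length` (FFT circular
  convolution) and rescaled to the requested mean and standard deviation.
  This gives smooth, spatially autocorrelated surfaces with exactly
  controlled moments, which is all the downstream machinery depends on.
* Land cover is one autocorrelated field sliced at its sample quantiles,
  so realised class shares match requested proportions within 0.03 while
  classes stay spatially coherent.
* Distance layers are Euclidean distances to randomly placed features.
* Telemetry fixes are independent draws from the cells with probability
  proportional to `exp(suitability)`, where suitability is an additive
  niche with step (threshold) and linear terms — the threshold responses
  that partial-dependence plots are designed to recover. Fixes land at the
  cell centre plus uniform within-cell jitter, so point-in-cell extraction
  is unambiguous. An animal's fixes have *no movement autocorrelation*:
  the downstream models treat fixes as exchangeable points, so independent
  draws are the matching null. Consequently, passing tests demonstrate
  that the pipeline recovers a known niche from exchangeable presence
  data; they do not demonstrate robustness to serially correlated
  movement, collar error, or fix loss, none of which the generator
  emulates.

The packaged reference scenario (`synthetic_scenario()`) is a 60 × 60 km
frame (120 × 120 cells) with one driving layer (`snow_day_fraction`,
mean 0.5, sd 0.15) whose step threshold is 0.7 with a 10-unit latent
contrast, plus an uninformative continuous layer and an uninformative
distance layer. Fourteen animals over one non-leap year give roughly 5,000
winter presences and, via density matching, a comparable number of
pseudo-absences. On this scenario the fitted model's holdout AUC exceeds
0.99, the driving layer is always the top predictor at importance 100.0,
and the partial-dependence positive range begins within one evaluation-grid
step of the true threshold (median over five seeds).

## Numerical choices and degenerate inputs

* `sd = 0` layers are exactly constant; rescaling to target moments is
  exact, not approximate.
* All-identical scores carry no ranking information; `balanced_threshold()`
  returns 0.5 in that degenerate case.
* IDW is exact at nodes (a cell whose centre coincides with a scored point
  takes that score), output is clipped to [0, 1], and when scoring points
  are the cell centres themselves — the usual case — the surface equals the
  scores.
* Rows with missing predictor values are excluded from fitting with a
  logged count; missing-data tolerance inside the trees is a property of a
  specific commercial implementation and is not relied on.
* Hyperparameters outside the customary search ranges (1000–2000 trees,
  6–20 nodes, 2–50 minimum cases) warn but are accepted.
* Rasters round-trip through plain-text ESRI ASCII grids at full double
  precision (`%.17g`).

## Problem sizes

The test suite runs the full pipeline at reduced sizes chosen to exercise
every code path with comfortable statistical margins: unit fixtures on
grids of 6–200 cells a side, pipeline runs on 40–60-cell grids with 300
trees, and the reference scenario at its full 120-cell, 1000-tree
configuration (five seeds) in the acceptance checks. These sizes are the
package's own validation design; the generator and models scale to larger
frames linearly in cells × trees.

## Known limitations

* The boosting learner reproduces the classical stochastic
  gradient-boosting contract, not any proprietary tool's exact trees, so
  importance *values* from other software will differ even though rankings
  and the validation metrics are comparable.
* Density matching can request more background cells than a small frame
  holds; the count is then capped with a warning (the background is the
  entire presence-free frame).
* The fixed km/degree constant is a reporting convention, not geodesy;
  at 67° N a longitudinal degree is ~44 km, so west–east deviations are
  conventional distances, comparable within the table that defines them.
* Selection ratios are computed from pooled binary maps; per-year
  ratio averaging (a "mean selection" column) is supported only as the
  mean of per-year tables the user computes, since it is not derivable
  from pooled areas.
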