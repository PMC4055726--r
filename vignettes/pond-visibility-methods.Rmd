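---
title: "Methods: road-viewshed visibility and classification trees for invasive-fish presence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: road-viewshed visibility and classification trees for invasive-fish presence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

pondsight models the presence of two invasive freshwater fishes in
agricultural ponds from the visual exposure of each pond to its surrounding
roads — a surrogate for the propagule pressure generated by anglers who
scout ponds from their vehicles — together with landscape and site
predictors. This vignette is the package's own account of the methods: the
viewshed definition, the landscape metrics, the classification-tree engine,
the synthetic-landscape generator that stands in for the original GIS and
survey data, and the numerical choices behind each.

## The visibility score

A pond's visibility is a cumulative viewshed statistic over a digital
surface model (DSM), an elevation raster that includes buildings and
canopy:

1. Observation points are placed every `spacing` (default 100 m) along road
   polylines, starting at each line's first vertex; each observer's eye sits
   `eye_height` (default 1.5 m) above the bilinearly interpolated surface.
2. A grid cell is visible from an observer when the straight line from the
   eye to the cell centre (at the cell's stored surface elevation) passes
   over every sampled surface point strictly between the endpoints. The
   surface is sampled every `los_step` (default half the cell size) by
   bilinear interpolation.
3. A cell's *viewshed count* is the number of observers within
   `max_distance` (default 500 m, horizontal distance) that see it; a
   pond's visibility score sums the counts of all cells whose centres fall
   inside the pond polygon.

Numerical rules, chosen for determinism and testability:

* **Strict-inequality blocking.** A sample blocks only when it lies
  strictly *above* the sight line; grazing rays count as visible.
* **Half-open sampling.** Samples are taken strictly between the endpoints,
  so neither the observer's own ground nor the target's own surface
  self-occludes; the observer's own cell is always visible.
* **Horizontal distance.** The 500 m limit is a map distance, as in common
  GIS viewshed tools; whether the original analysis used slant distance is
  unknowable from the text, and the choice is configurable.
* **No target offset.** The target is the bare water/ground parcel; only
  the observer carries an eye-height offset.
* **Nodata blocks nothing and is never visible.**

The production path is a compiled kernel; `line_of_sight()` and
`viewshed_counts_reference()` are a plain-R reference implementation of the
identical definition, kept as an independent oracle. The test suite and the
acceptance script require cell-for-cell agreement between the two on rough
random terrain, and exact agreement with the within-radius closed form on
flat terrain. Agreement with any particular GIS product's viewshed is *not*
claimed: interpolation and tie rules differ between tools, and only this
package's published definition is the contract.

## Landscape metrics

All geometry is planar Cartesian metres; no geographic CRS handling.

* **Ring buffers.** Predictor densities are measured in the zone within a
  buffer distance *outward* of the pond's edge, excluding the water surface
  itself — including the pond would dilute road and river densities by open
  water. The exclusion is the package's reading of "within 500 m of the
  pond edge"; it is a documented choice, and the buffer polygon carries the
  pond ring as a hole so either convention can be recomputed. Buffers are
  exact convex offsets with vertex arcs sampled to a chord sagitta below
  `distance/256` (≈0.3% area error on a fully rounded corner). Pond
  polygons are convex by construction in this package.
* **Road density / river density**: clipped line length over ring area
  (m/m²; exported in the display unit 10⁻³ m/m²). River density is
  profiled over graded buffers of 5, 10, 25, 50, 100, 250, 500 and 1000 m.
  Clipping cuts each segment at every ring-edge crossing and keeps
  sub-intervals whose midpoints lie inside (even-odd rule, boundary counts
  as inside).
* **Urban ratio**: fraction of land-use raster cells with centres inside
  the ring buffer that are urban. Computed on the raster representation;
  the rasterisation error bound (2 · perimeter · cell size) is asserted in
  tests.
* **Connectivity with upstream reservoirs** is a path-type property on a
  typed directed graph: class 2 when some reservoir reaches the pond
  through canal nodes only, class 1 when it is reachable but only through
  intermediate ponds or farmland, class 0 when unreachable. When both a
  direct and a mediated route exist, direct wins. Reachability is the
  operational definition of "indirect supply"; no hydrological modelling is
  attempted.
* **Trophic state**: hypertrophic at chlorophyll *a* ≥ 25 µg/L, eutrophic
  in 8–25 µg/L; below 8 µg/L the package uses the label `sub_eutrophic`,
  an artifact convention for a band the source categorisation leaves
  unnamed.

## The classification-tree engine

Presence/absence is modelled with binary CART: greedy Gini splitting,
weakest-link cost-complexity pruning, k-fold cross-validation, and the
1-SE rule, re-implemented in full (the installed `rpart` serves only as an
independent cross-check in one test).

* **Growing.** Numeric splits are searched at midpoints of consecutive
  distinct sorted values; categorical splits over all proper subsets of the
  levels observed at the node. Defaults `min_split = 20`, `min_leaf = 7`,
  `max_depth = 30` — the conventional controls, which matter at n = 64.
  Ties in impurity decrease (within an absolute tolerance of 1e-8 on the
  count scale) resolve to the earliest declared variable, then the smallest
  threshold, so growing is fully deterministic. Cases with value below the
  threshold go left; rules print as "variable ≥ t → right".
* **Pruning.** Weakest link: repeatedly collapse the internal node(s)
  minimising g(t) = (R(t) − R(T_t)) / (|leaves| − 1), risks scaled by the
  root risk so the null model scores exactly 1. The α = 0 entry of the
  path is the smallest cost-complexity-optimal tree at α = 0: splits that
  improve Gini but not misclassification (g = 0) are collapsed into it,
  which keeps the α sequence strictly increasing; on separable data the
  entry is the literal grown tree.
* **Cross-validation.** A seeded uniform (non-stratified) partition into
  k = 10 folds; each fold's tree is pruned at the geometric-mean alphas of
  the master path and scored on the held-out cases. `xerror` is pooled
  held-out misclassification over the full-data root risk; `xstd` is the
  per-case-loss standard error on the same scale (numerically identical to
  the convention of the reference tool, verified against it).
* **1-SE rule and the modal tree.** The selected size is the smallest
  whose `xerror` is within one standard error of the minimum. To remove
  fold-partition luck, 50 cross-validations are run with consecutive seeds
  and the *mode* of the selected sizes is used (ties to the smaller size);
  the full-data tree pruned to that size is reported. "Modal tree" is
  operationalised as modal *size* — the identity of a tree across repeats
  is otherwise ill-defined — and the vote table is attached to the result.
* **Evaluation** is on the full dataset (apparent error), reported as
  misclassification %, sensitivity and specificity; display rounding is
  half-away-from-zero (0.925 prints as 0.93), exact fractions are retained.
* Connectivity enters the trees as an unordered categorical variable by
  default (an ordinal treatment is a one-line change in the caller).
  Pond area enters untransformed: trees are invariant to monotone
  transforms, a property the suite asserts.

## The synthetic landscape generator

The generator replaces the study's GIS layers and fish surveys with a
seeded artificial landscape carrying the same statistical structure, so
every stage of the pipeline is testable end to end.

What it emulates: a 3 km × 3 km projected landscape; hills (Gaussian
bumps, 10–80 m); a southern urbanised strip (18% of the extent) filled
with 5–15 m building blocks; a woodland belt (36%) with 5–15 m blocky
canopy; a jittered road grid (500 m spacing, denser in the urban strip)
whose corridors are carved free of obstacles; two meandering rivers; 64
convex ponds with log-uniform areas spanning 685–111,626 m²; a
reservoir–canal graph wiring ~30% of ponds directly and ~22% indirectly;
truncated log-normal chlorophyll *a* spanning 1.9–438.8 µg/L (median
≈26 µg/L); and a 42% winter-drainage rate. All randomness flows from one
seed through named substreams (terrain / buildings / roads / ponds /
rivers / canals / attrs / labels), so any layer can be regenerated
independently and byte-identical reruns are guaranteed.

Presence labels are *planted decision rules that mirror the fitted
structure the pipeline is meant to recover*, not a causal ecology: the
bluegill-like species is present when the pond is reservoir-connected OR
its visibility reaches the 0.75 visibility quantile; the bass-like species
when chlorophyll *a* is at most 38.25 µg/L AND a Bernoulli introduction
event occurs; every label is then flipped with probability 0.10.

Two generator parameters deserve their rationale spelled out:

* **Introduction probability 0.7 (bass-like species).** Under equal-loss,
  observed-prior CART, a planted conditional rule is recoverable only if
  the rule-satisfying leaf is majority-present. An introduction probability
  below 0.5 makes the below-ceiling leaf majority-absent and the planted
  chlorophyll rule undiscoverable *by construction*; 0.6 leaves the leaf at
  ~58% present, a margin thin enough that the modal tree misses the rule in
  a material fraction of landscapes. The generator's design contract is
  that its planted rules are recoverable by the engine it feeds, so 0.7
  (a ~66% leaf) is used. The cost is prevalence: the bass-like species
  settles near 44% of ponds rather than the ~19% of the emulated study —
  that historical prevalence, produced by a tree whose present-leaning
  leaves were minority-present, is not reproducible by an equal-loss
  engine at all, and recoverability was chosen over prevalence matching.
* **Threshold-in-gap rates.** After recovery, one can ask whether the
  learned numeric threshold lies in the data gap bracketing the planted
  value. At 10% label noise this has a hard ceiling: one flipped label
  adjacent to the boundary already moves the empirical Gini optimum past
  the bracketing gap (probability ≈ 1 − 0.9² from the two adjacent points
  alone), and the bass rule's Bernoulli gate spreads its split position
  further. The recovery report computes these rates rather than asserting
  them reachable; halving the noise rate roughly halves the adjacent-flip
  probability and lifts the ceiling accordingly.

What the generator does *not* emulate: real hydrology or flow direction,
actual Japanese basemaps, photogrammetric DSM artefacts, seasonal water
supply, or the empirical joint distribution of the study's predictors.
Passing tests therefore demonstrate that the pipeline measures what it
defines and recovers structure it is pointed at — not that it would
reproduce the original study's fitted trees, whose data are unavailable.

## Problem sizes used by tests and the acceptance script

The suite exercises the viewshed oracle on 20 random 64 × 64 DSMs with 5
observers; the tree grower against an exhaustive oracle on 50 random
datasets (n ≤ 30); pruning contracts on 40 random trees; and the
end-to-end recovery study on 25 independent coarse landscapes (5 m DSM
cells, 200 ponds of 685–15,000 m² so that 200 fit a 3 km extent, 10%
label noise, 50 repeated cross-validations per tree). The coarse
resolution and the reduced pond-area range for the 200-pond study are the
package's desk-scale choices; the 64-pond default configuration keeps the
full study area ranges.

## Known limitations

* Viewshed counts are exact with respect to this package's ray-sampling
  definition, not to any commercial tool's output.
* `buffer_polygon()` requires convex exteriors (synthetic ponds are convex
  by construction); concave pond shapes would need a general offset
  algorithm.
* GeoTIFF input is not implemented — ESRI ASCII is the canonical raster
  format here; land-use input is the category raster, not polygons.
* Surrogate splits, case weights, loss matrices and missing-value handling
  are out of scope: synthetic inputs are complete by construction.
* Apparent (resubstitution) error is the reported model performance, as in
  the emulated design; a held-out protocol would need more ponds than the
  64-pond default provides.
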