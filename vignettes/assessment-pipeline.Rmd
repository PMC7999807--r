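---
title: "Preliminary Red-List screening and EDGE prioritization: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preliminary Red-List screening and EDGE prioritization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endemicrisk)
```

## The problem

National endemic floras are routinely too large, and their occurrence data
too heterogeneous, for taxon-by-taxon Red List assessments: a flora of a
thousand-plus endemics would need decades of committee work. What occurrence
databases *can* support is a fast, preliminary screening under the two IUCN
criteria that need only georeferenced records and a land-cover map —
Criterion B (restricted geographic range) and Criterion A (inferred
population reduction) — followed by phylogenetically informed
prioritization with the EDGE index and a mapping stage that shows where the
threatened and evolutionarily distinct taxa actually are, inside or outside
the protected-area network. `endemicrisk` implements that workflow
end-to-end. Its output is a *screening*, not a substitute for full Red List
assessments: the package's category labels are preliminary by construction
and should be read as triage.

## Criterion B: range geometry

All geometry runs on a Lambert azimuthal equal-area projection (spherical
formulas on the authalic sphere) so areas are in honest km². The data name
no CRS, so the projection centre is configurable and defaults to the
occurrence centroid; a unit test checks that a 1° geodesic square at the
domain centre keeps its ellipsoidal area to within 0.5% after projection.
Exact duplicate records are collapsed before any geometry — occupancy, not
record count, is what the measures are defined on.

Per taxon we compute:

* **EOO** — the area of the minimum convex polygon around the points.
  Fewer than three non-collinear points give EOO 0, flagged degenerate.
* **AOO** — occupied 2 × 2 km grid cells × 4 km² (the IUCN reference
  scale). Cells are half-open intervals, so boundary membership is
  unambiguous.
* **Locations** — occupied 10 × 10 km cells. The IUCN's location concept is
  threat-based; occurrence records carry no threat geometry, so a
  deterministic coarse-grid proxy is used and documented. The grid origin
  defaults to the projection origin and is part of the configuration, so a
  run is exactly reproducible.

At assessment time the *EOO floor* is applied first
(`effective EOO = max(EOO, AOO)`), which also absorbs the degenerate-EOO
case. Sub-criterion B1 tests effective EOO against 100 / 5 000 / 20 000 km²
and B2 tests AOO against 10 / 500 / 2 000 km², each jointly with location
counts 1 / 5 / 10; the category is the more severe of the two, and the
continuing-decline condition is assumed satisfied, as in automated
ConR-style screenings. The thresholds live in one editable table
(`criterion_b_thresholds()`), never in the logic.

**The NT band.** The IUCN criteria give no numeric rule for Near
Threatened. This package assigns NT when the VU cutoffs are missed by at
most 50% (effective EOO < 30 000 km² or AOO < 3 000 km², with ≤ 15
locations), otherwise LC. We enable this buffer by default — a screening
that can never emit NT would collapse a category that real reference
assessments use, and the synthetic designs span it — but it is a package
convention, clearly separated in the threshold table and removable with
`nt_buffer = FALSE`.

## Criterion A: habitat-threat proxy

Population-level data are rarely available for plants, so potential
population reduction is inferred from habitat: the fraction of a taxon's
occupied 2-km cells whose land cover is dominated by classes of
moderate-to-high human influence (in a CORINE-style nomenclature: the
artificial and agricultural classes, *excluding* olive-grove and mixed
agricultural/natural classes, which behave as semi-natural habitat for
Mediterranean endemics). The reduction percentage maps onto the Criterion
A2 cutoffs 80 / 50 / 30%, with a configurable NT band at 20%.

Resolution rules the data sources leave open, fixed here and recorded in
every run manifest:

* raster layers use a **pixel-count majority** within the cell (ties go to
  natural — the conservative direction for a threat proxy); polygon layers
  use the class at the cell centroid;
* cells without land-cover data leave the denominator and are counted; a
  taxon with only unknown cells is DD under this criterion;
* the unit of analysis is the occupied AOO cell (matching the
  "potential decrease in AOO" reading); a per-occurrence mode exists for
  sensitivity analysis (`unit = "occurrence"`);
* the proxy is a static habitat-quality snapshot; no 10-year/3-generation
  window is modelled, because a single land-cover epoch cannot support one.

## Combination and validation

The combined category is the maximum-severity join of the two criteria
(CR by either criterion means CR overall); DD on one side defers to the
other. For validation the categories are aggregated into threatened
(CR ∪ EN ∪ VU) versus not (LC ∪ NT) and compared with a reference
assessment table in a 2 × 2 confusion matrix with threatened as the
positive class, reporting accuracy and sensitivity (plus specificity and
balanced accuracy as labelled extras). DD rows on either side are excluded,
as are unmatched taxa, both with counts.

## ED and EDGE

Evolutionary distinctiveness is the fair-proportion apportionment: each
branch of the time-calibrated tree is divided equally among the tips below
it, and a tip's ED (Myr) is the sum of its shares along the root-to-tip
path. Summed over tips this returns the tree's total branch length exactly
— the property the test suite asserts to 1e-9 on random birth–death trees,
alongside a path-walk oracle and a cross-check against
`picante::evol.distinct`. Polytomies are apportioned as given.

The EDGE score is `ln(1 + ED) + GE · ln 2` with GE the category weight
LC = 0, NT = 1, VU = 2, EN = 3, CR = 4: one category step doubles the
modelled extinction risk, adding exactly ln 2. Natural logarithms
throughout. The GE weight uses the **combined** category — the screening
assesses every taxon under both criteria, and the combined label is the
assessment the rest of the pipeline reports; this is an interpretation this
package fixes explicitly. Taxa absent from the tree get no score and are
counted; DD taxa get no score and are excluded from spatial means.

## Grid surfaces, L1 hotspots, PA gap

Occurrences are gridded at 5 × 5 km (presence, not abundance). Each
occupied cell carries endemic richness, threatened richness, CR richness
and the arithmetic mean EDGE over the scored taxa present. For each metric
the **L1 hotspots** are the top 1% of eligible cells: the threshold is the
k-th largest value with `k = ceiling(0.01 · n_eligible)` and ties at the
threshold are included, so hotspot sets can slightly exceed 1%.

Eligibility defaults to *occupied cells only*. A national domain is mostly
cells with no endemic at all (sea, non-habitat); taking the quantile over
all cells would make "top 1%" trivially equal "any occupied cell". The
alternative (`eligible = "all"`, with unoccupied cells as zeros) is
provided for comparability. For the EDGE metric, cells with no scored
taxon have no mean and are ineligible.

A hotspot cell is inside the protected-area network iff its full 5-km
square geometrically intersects a PA polygon (centroid mode available);
the reported gap is the percentage of hotspot cells outside. Intersection
uses an exact rectangle-polygon predicate (vertex containment plus edge
crossing), not sampling.

## The synthetic scenario generator

The occurrence database this kind of study runs on is typically
proprietary, and the land-cover and PA products are bulky downloads — so
the package carries a generator that emulates the *structure* of the
inputs, making every stage testable offline. A scenario is a (config,
seed) pair; one master seed is split once into five documented sub-streams
(occurrences, land cover, tree, PAs, reference subset), and two runs with
the same seed are byte-identical through the whole pipeline.

Designed categories work through the location grid, which makes them exact
by construction rather than statistically: a CR taxon is one tight cluster
(points in a 1.2 km disc at a 10-km cell centre — 1 location, hull < 5 km²);
EN, VU, NT and LC taxa scatter 2–4, 7–10, 11–15 and 16–24 such clusters
over windows whose extent keeps the convex hull below the relevant EOO
cutoff (60 × 60 km for EN, 120 × 100 for VU, 160 × 140 for NT, the whole
domain for LC). Because the location count alone already separates the
categories, recovery by the Criterion B stage is expected at 100% and the
acceptance suite requires ≥ 95%.

Scenario defaults sketch a Mediterranean national setting and are stated
once, here: a 500 × 400 km domain centred at 24°E 38.5°N; 200 taxa with
category mix CR 20 / EN 20 / VU 20 / NT 15 / LC 25%; 8 points per cluster
(enough for stable hulls, small enough to keep tests fast); a 1-km
land-cover mosaic with 30% threat classes (of the order of the artificial
plus intensive-agricultural share of a Mediterranean country); protected
areas as non-overlapping 20-km squares covering 28% of the domain (a
typical national terrestrial PA coverage); a pure-birth tree rescaled to a
100 Myr root. The mosaic is spatially unstructured (i.i.d. pixels), so
per-taxon Criterion A reductions concentrate near the landscape threat
fraction — unlike real landscapes, where land-use clustering puts some
taxa almost entirely in converted habitat. Passing tests therefore
demonstrate correctness of the *computations*, not realism of any
particular national flora's spatial statistics (range-size frequencies,
beta diversity and land-use autocorrelation are all out of scope of the
generator).

## Numerical conventions

* Half-open grid cells on both axes; a boundary point belongs to the
  higher-index cell.
* Criterion thresholds: range measures use strict `<`, locations and
  reductions use `≤`/`≥`, matching the IUCN tables' wording.
* Raster majority ties resolve to natural; hotspot threshold ties are
  inclusive.
* Degenerate EOO (collinear or < 3 points) is 0 and resolved by the EOO
  floor, never by a special category.
* An all-equal hotspot metric makes every eligible cell a hotspot, with a
  warning.

## Problem sizes in the shipped checks

The test suite and the acceptance script exercise: 100 random point sets
(n ≤ 50) against an O(n³) hull oracle; an exhaustive 2 700-point threshold
lattice for Criterion B; 50 random birth–death trees (≤ 128 tips) for ED
conservation; 100 random surfaces for the hotspot oracle; and a 200-taxon
full-pipeline scenario. These sizes give each property enough room to fail
while keeping a full run in the order of seconds to a minute.

## Limitations

* Criterion B's location proxy and assumed continuing decline, and
  Criterion A's static habitat proxy, are screening conventions — both can
  only be resolved by taxon-level threat data.
* No severe-fragmentation test, no subpopulation structure, no Criteria C
  and D (they need population-level data).
* Land-cover change between epochs is not modelled.
* The GeoJSON layer handles single-ring polygons only, which covers the
  PA-network and hotspot interfaces but not multipolygon coastlines.
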