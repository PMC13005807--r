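---
title: "Methods: exposure windows, spatial scan statistics and the synthetic registry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exposure windows, spatial scan statistics and the synthetic registry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package addresses

Chronic immune-mediated diseases such as type 1 diabetes develop over years,
so the residential environment that matters for aetiology may be the one
experienced long before diagnosis. Registry studies that geocode only the
address at diagnosis risk misclassifying exposure: in high-incidence
national cohorts roughly a quarter of cases change municipality between
birth and diagnosis. This package implements the full analytical chain for
studying geographic risk with *longitudinal* residential histories — one
location per case-year from birth to diagnosis — and for asking in which
life stage the spatial signal is strongest.

## Life-stage exposure windows

Four windows are defined per case: `at_diagnosis` (the diagnosis year),
`first5` (birth year through birth year + 4), `last5` (diagnosis year − 4
through diagnosis year) and `lifetime` (birth through diagnosis). All bounds
are inclusive calendar years, matching the one-location-per-year resolution
of registry linkages. Design choices worth stating explicitly:

- **Truncation, not exclusion.** A case diagnosed before age five has its
  `first5`/`last5` windows truncated at the diagnosis/birth year rather than
  being dropped, since the cohort includes ages 0–30 in every window.
- **Dominant location.** Within a window the representative cell is the one
  occupied the most years; ties go to the cell occupied earliest within the
  window. The tie-break is arbitrary in principle but must be fixed: this
  one is deterministic and invariant to row order, which the test suite
  verifies by permutation.

## Areal incidence mapping

Unit-level crude incidence is `cases / (mean population × period years) ×
100,000`. Expected cases are `population × national incidence × period`,
with the national incidence computed from the analysed dataset itself so
that observed and expected totals balance exactly — the
observed-vs-expected map is then a purely internal comparison, and its
population-weighted mean difference is zero by construction. Display
classes use quintile breaks at the 20/40/60/80th percentiles with linear
interpolation between order statistics (R's default type-7 quantile), ties
assigned downward, and a top-2% flag with a closed (≥) comparison against
the 98th percentile; when all values are equal the flag is therefore true
everywhere, a documented degenerate case. Direct standardisation is a
reference-weighted sum of stratum crude rates and reduces to the crude rate
when stratum rates are homogeneous.

## The discrete-Poisson spatial scan

Candidate windows are circles centred on grid-cell centroids: for each
centre, neighbours are sorted by Euclidean distance (ties by cell id) and
the window grows one cell at a time, stopping before any addition that
would push the window population above 5% of the total or a member beyond
100 km. Every singleton is a candidate. With in-window observed count `c`
and expectation `E` proportional to window population share, the one-sided
log-likelihood ratio is `c·ln(c/E) + (C−c)·ln((C−c)/(C−E))` when the
direction condition holds and zero otherwise. Inference is by Monte Carlo:
each replication redistributes the `C` cases multinomially with cell
probabilities proportional to population, the replication's maximum LLR
over the *same* candidate set is recorded, and the p-value is the rank of
the observed statistic, `(1 + #{max ≥ observed})/(R + 1)`. This rank
construction is exact by exchangeability, which is what the 200-dataset
Type-I calibration in the acceptance suite checks. Secondary clusters are
selected greedily in decreasing LLR order subject to sharing no cell with
an already-reported cluster (the strictest no-overlap rule); ties prefer
the smaller window, then the lower centre cell id. High- and low-risk scans
are separate one-sided analyses, each with its own null distribution.
Coordinates are planar metres throughout (mirroring a national transverse
Mercator projection); no geodesic correction is applied. The p-value grid
is fixed at `1/(R+1)`; no tail approximation is used. The per-window and
per-replication loops are compiled (Rcpp) because a pure-R implementation
cannot run the calibration studies in reasonable time; the algorithm itself
is implemented from scratch and is checked against an independent
brute-force maximiser on small grids.

## The synthetic registry generator

The generator emulates the statistical structure of a national incidence
registry without reproducing any real geography:

- **Grid and units.** A regular lattice (default 1 × 1 km cells) partitioned
  into contiguous rectangular administrative units; about one in ten units
  is "urban" and receives `urban_fraction` (default 50%) of the expected
  population; cell populations are Poisson draws and empty cells are
  excluded, as registry grids exclude uninhabited cells.
- **Cohort.** One simulated person per unit of population; ages uniform
  over 0–30 at the period start; population static over time (registry
  municipal populations vary little over such periods, and a constant
  denominator keeps person-years = population × years).
- **Mobility.** Each year a person moves with probability
  `relocation_prob`, the destination drawn population-weighted over all
  cells, which reproduces urban-ward drift without extra parameters. The
  default 0.018 was calibrated once, by the same binary search the
  acceptance suite performs, so that ≈24% of cases change administrative
  unit between birth and diagnosis.
- **Onset.** A constant per-person-year hazard of 36/100,000, multiplied by
  the `risk_multiplier` of any planted circular cluster whose circle
  contains the person's *dominant residence within the cluster's active
  window*, evaluated relative to the candidate onset year. Using the same
  dominance rule on both the planting and detection side makes planted
  relative risks recoverable without attenuation; this is the package's
  resolution of an ambiguity (which residence counts for a multi-year
  window) that a real registry would not face.
- **Defaults as a stated world.** The default scenario (40 × 40 grid,
  400,000 persons, 18 study years) yields roughly 1,900 cases, i.e. a
  demo-sized registry; sex and nativity flags use the published cohort
  margins (57.7% male, 76.2% native).

What a green test establishes — and what it does not: the generator has
uniform age structure, no secular incidence trend, no seasonality, no
within-year moves, and mobility independent of disease status; recovery of
planted clusters therefore validates the *inference machinery*, not the
epidemiology of any real cohort. Because ages are uniform at period start
and persons age out at 30, registry-style crude rates computed with the
full population × years denominator understate the true cohort hazard; the
generator's incidence calibration is asserted against exact simulated
person-years (exposed as an attribute), while the mapping stage keeps the
registry convention — both are internally consistent and the discrepancy is
deliberate.

## Land cover and cartogram

The land-cover raster is categorical with a configurable 17-class legend
mapped onto five aggregate classes (Urban, Agriculture, Forest, Open land,
Lakes and streams); the shipped legend is synthetic but uses the named
classes of national land-cover products. Zonal histograms use cell-centre
containment (the standard zonal convention); a circle containing no cell
centre falls back to the cell containing the circle centre. Group means
across clusters are unweighted, matching a "mean share within each group"
contract; area- or population-weighting would be a one-line switch. Because
no raster library is assumed, rasters are stored as plain-text ESRI ASCII
grids.

The Dorling cartogram scales circle radii as `k·√population` (one global
`k`, so areas are value-true) and relaxes positions iteratively: pairs
overlapping by depth `d` repel along their centre line by a damped `d/4`
each; circles not involved in any overlap are attracted toward their seed
centroids by 5% of the remaining displacement per sweep. Iteration order is
fixed by unit id, coincident centres separate along a fixed axis, and the
maximum overlap per sweep is logged as a convergence diagnostic. Any
overlap-free, area-true layout satisfies the visual contract; the defaults
(tolerance 1 m, ≤500 sweeps) converge on all tested configurations.

## Numerical and degenerate-input conventions

- `0·ln 0 = 0` in the LLR; windows with `E ≤ 0` or `E ≥ C` contribute 0 and
  are rejected by the validating R-level function.
- `RR = Inf` is flagged (not an error) when all cases fall inside a window.
- Quintiles require ≥5 units; rates require positive person-years; an empty
  case table is valid input everywhere until the scan, which raises a
  no-cases error.
- All randomness derives from one run seed via deterministic per-stage
  sub-seeds (kept below 2³¹), so every stage is bit-reproducible and stages
  can be re-run independently.

## Known limitations

- The circular window family cannot represent elongated clusters except as
  unions of reported circles; elliptic or irregular windows are out of
  scope.
- Monte Carlo p-values have resolution `1/(R+1)`; with 999 replications the
  smallest attainable p is 0.001.
- The generator's constant-hazard, static-population world ignores cohort
  aging effects on the denominator (see above) and immigration dynamics.
- Confidentiality-motivated redaction of small clusters, real coordinate
  reference systems, and address-level geocoding are intentionally not
  modelled.
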