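# t1dscan

Geospatial analysis of disease incidence from longitudinal residential
histories, built around the study design used for type 1 diabetes registries:
every case contributes one residential location per year of life from birth
to diagnosis, and the question is *where* risk is elevated or reduced, and
*when in life* the relevant exposure happened.

The package provides, as a tested and reusable pipeline:

- **Life-stage exposure windows** — for each case, the representative
  residential grid cell in four windows: residence in the year of diagnosis,
  the dominant (most-years) residence in the first 5 years after birth, in
  the 5 years prior to diagnosis, and from birth to diagnosis.
- **Areal incidence mapping** — per administrative unit: crude incidence per
  100,000 person-years, expected cases (population × national incidence ×
  period), observed-vs-expected percentages, quintile display classes and a
  top-2% flag, plus direct age/sex standardisation and nativity
  stratification.
- **A from-scratch discrete-Poisson spatial scan statistic** — circular
  windows over grid-cell centroids, grown one neighbour at a time up to a
  population cap (default 5%) and radius cap (default 100 km); one-sided
  high- and low-risk scans; Monte Carlo p-values from multinomial
  replications (default 999); greedy non-overlapping secondary clusters;
  relative risks. The per-replication maximisation is compiled (Rcpp).
- **Land-use/land-cover profiling** — reclassification of a 17-class
  categorical raster to five aggregate classes (Urban, Agriculture, Forest,
  Open land, Lakes and streams), zonal histograms of cluster circles, and
  per-group mean shares.
- **Dorling cartogram layout** — one circle per unit, area proportional to
  population, iteratively relaxed until circles no longer overlap.
- **A synthetic registry generator** — a population grid with urban
  concentration, a yearly relocation process, a constant baseline hazard
  (default 36 cases per 100,000 person-years over an 18-year period, ages
  0–30) and plantable circular risk clusters active during configurable life
  stages, providing ground truth for parameter-recovery tests.

## The statistic at the core

For a candidate circular window with observed cases `c`, expected cases
`E = C · (window population / total population)` and total cases `C`, the
one-sided discrete-Poisson log-likelihood ratio is

```
LLR = c·ln(c/E) + (C − c)·ln((C − c)/(C − E))    if c > E (high) / c < E (low)
LLR = 0                                          otherwise
```

The most likely cluster maximises LLR over all windows; significance is the
Monte Carlo rank of the observed maximum among replication maxima:
`p = (1 + #{replications ≥ observed}) / (R + 1)`. The relative risk of a
window is `RR = (c/E) / ((C−c)/(C−E))`.

## Worked example

```r
library(t1dscan)

cfg <- scenario_config(grid_nx = 30, grid_ny = 30, n_units = 9,
                       total_population = 212000,
                       planted_clusters = list(
                         planted_cluster(7000, 22000, 3200, 2, "first5")),
                       seed = 212)
grid  <- generate_grid(cfg)
cases <- generate_case_histories(grid, cfg)
attr(cases, "n_cases")
#> [1] 1030

a <- assign_windows(cases)
counts <- table(factor(as.character(a$cell_id[a$window == "first5"]),
                       levels = as.character(grid$cell_id)))
cl <- scan_poisson(grid, as.numeric(counts),
                   scan_config(direction = "high", n_replications = 999,
                               seed = 212))
cl[, c("centre_cell", "radius_m", "n_cells", "c", "E", "rr", "p_value")]
#>   centre_cell radius_m n_cells  c        E       rr p_value
#> 1         667     3000      27 43 17.18365 2.567832   0.001
```

The generator planted a circle of radius 3.2 km at (7000, 22000) whose
residents (by dominant residence in their first five years of life) face a
doubled hazard; the scan recovers a 27-cell cluster containing that centre
with 43 observed versus 17.2 expected cases, an estimated RR of 2.57, and
the smallest attainable Monte Carlo p-value (1/1000). The full pipeline —
simulation, window assignment, unit incidence, all eight scans, land-cover
profiles and the cartogram — runs from one configuration via
`run_pipeline(list(scenario = cfg, scan = scan_config()), "out/")`.

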