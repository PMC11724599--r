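# mullettrack

Analysis toolkit for passive acoustic-telemetry studies of seasonally
resident coastal fish, built around a two-species grey mullet study design:
thicklip and thinlip mullet tagged in a focal coastal sea (a Wadden-Sea-like
basin monitored by a dense receiver array), with sparser marine arrays along
the adjacent coast and a single freshwater receiver behind a sluice barrier.

The package answers the questions such studies ask: when do tagged fish
arrive and depart each season, how intensively do they use the monitored
area, how far do their movements extend, how are the regions connected, and
do sympatric species differ?

## What it implements

* **False-detection filtering** — a five-rule cascade applied in fixed
  order: pre-deployment records, exact duplicates, records violating the
  tag's minimum transmission delay, 24-hour singletons, and records of fish
  that died. Damaged or briefly deployed stations (< 90 days) are excluded
  from occurrence and station-level analyses. Every rule's removals are
  reported and reconcile exactly.
* **Residency metrics** — per fish-year arrival/departure (first/last
  detection, return years only for timing statistics), inclusive residence
  duration, detection days, the residency index
  `RI = detection days / residence duration` in (0, 1], the per-station
  local residency index `RI_stat = days at station / days in array`, and
  per-station medians over eligible fish-years (duration > 5 days).
* **Space use** — 100% minimum convex polygons over the stations at which a
  fish was detected (> 5 days at >= 3 stations per year), shoelace areas in
  km², corrected for overlap with a land mask.
* **Connectivity** — cross-region movement events from adjacent detection
  pairs, classified as outbound/inbound relative to the focal region,
  weighted origin-destination edge lists, and weekly/monthly unique-fish
  presence summaries.
* **Statistics** — tie-corrected Kruskal–Wallis rank-sum tests
  (chi-square approximation) with Dunn/Bonferroni post-hoc comparisons,
  written from the closed forms:
  `H = [12/(N(N+1)) Σ R_i²/n_i − 3(N+1)] / (1 − Σ(t³−t)/(N³−N))`.
* **A ground-truth simulator** — deterministic generator of receiver
  networks, fish trajectories (station-anchored daily random walks inside
  seasonal residence windows), transmissions with uniform random delays, a
  shifted log-logistic detection-range curve anchored at the 149 m midpoint
  and 610 m maximum range, tag mortality, and labelled injected noise
  (false positives, echo duplicates, sub-delay ghosts) for validating the
  filters and estimators.

## Worked example

Simulate a small two-season study (20 thicklip + 8 thinlip, coarse
30–60 min tag delay to keep the table small), run the full pipeline, and
summarise it:

```r
library(mullettrack)

cfg <- pipeline_config(sim = simulation_config(
  seed = 42, n_fish = c(thicklip = 20L, thinlip = 8L), n_years = 2,
  min_delay_s = 1800, max_delay_s = 3600,
  n_false_positives = 10, n_echo_duplicates = 10, n_subdelay_ghosts = 10))
bundle <- run_pipeline(cfg)
print(bundle$filter_report)
#> False-detection filter report
#>   input: 12911 records, output: 11884 records
#>   predeployment    examined    12911  removed      0
#>   duplicates       examined    12911  removed     10
#>   min_delay        examined    12901  removed     10
#>   singletons_24h   examined    12891  removed     24
#>   mortality        examined    12867  removed    983
#>   cross-station simultaneities retained: 0
#>   stations excluded from occurrence analyses: 6
```

All 30 injected noise records are gone — 10 by the duplicate rule, 10 by the
minimum-delay rule, 10 among the 24 singletons (the other 14 are genuinely
isolated true records, which the rule is supposed to drop) — and the 983
mortality removals are the two fish that died with pinging tags.

```r
pipeline_report(bundle)
#> Detections by region (fish / stations / detections):
#>       region n_fish n_stations n_detections
#>   wadden_sea     27         82        10416
#>    north_sea     26         20         1329
#>  fresh_water      6          1          139
#>
#> Return-year residence by species (median, IQR):
#>   species n_fish_years arrival_doy_median ... RI_median
#>  thicklip            7              169.0 ... 0.2542373
#>   thinlip            2              131.5 ... 0.4258939
```

The region block is the study's audit trail (how many fish, stations and
detections per region); the species block gives the return-year medians:
thinlip arrive earlier (day-of-year ~131 vs ~169) and are detected on a
larger share of their residence days (RI ~0.43 vs ~0.25). The species
contrast in RI is tested with the rank-sum machinery:

```r
ret <- subset(bundle$residence, included & is_return_year)
compare_species(ret, "RI")$kw
#> Kruskal-Wallis rank-sum test: chi-squared = 4.2, df = 1, p = 0.04042
#>   group sizes: thicklip=7, thinlip=2
```

## The analysis workflow

`analysis/` holds the numbered drivers that reproduce the full study-scale
workflow on simulated data, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # cohort + arrays + noise + ground truth
Rscript analysis/02_filter.R       # cascade + truth scoring
Rscript analysis/03_residency.R    # arrival/departure, RI, station medians
Rscript analysis/04_space_use.R    # station counts, land-clipped MCPs
Rscript analysis/05_connectivity.R # movement events, edges, presence
Rscript analysis/06_stats.R        # species comparisons
```

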