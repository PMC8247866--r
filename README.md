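# migvar

Individual-level analysis of migratory-behaviour variation from multi-year
GPS tracking.

Tracking studies of species with diverse migration strategies — the
motivating system is the lesser black-backed gull, where one colony holds
both 50-km and intercontinental migrants — ask whether individuals follow
consistent personal strategies or adjust year to year, and whether the
balance depends on migration distance. `migvar` answers this with the full
chain of standard movement-ecology machinery, implemented as composable R
functions:

- **Track ingest**: delimited-text GPS fixes, equal-area azimuthal
  projection, 12-h subsampling, non-breeding season splitting (10-km colony
  radius), and the inclusion filters (21-day gap rule; at least two seasons
  per individual).
- **Space use**: fixed bivariate-normal kernel utilization distributions
  (10-km grid, *h* = 100 km), 50% core areas and wintering-area assignment
  (December–March dwell), Bhattacharyya affinity of 95%-truncated UDs for
  across-year overlap, and a biased-random-bridge UD (500-m grid,
  *T*max = 3 h, *L*min = 20 m, *h*min = 150 m) for fine-scale winter site
  fidelity.
- **Routes**: per-individual 500-point mean migration routes minimizing
  nearest-neighbour distance to the yearly tracks (stopovers collapsed to
  centroids; 24-h gap rule) and a route-variation statistic in km.
- **Phenology and repeatability**: the four timing traits per season,
  REML mixed models (`lme4`) with colony and individual random intercepts,
  repeatability *R* = s²ₐ/(s²ₐ+s²ᵦ) with 1,000-iteration parametric
  bootstrap CIs, and individual-level *R*ᵢ.
- **Population statistics**: 250-km distance-constrained between-individual
  pairing, 10,000-iteration randomization tests on differences of medians,
  distance regressions (F and LRT), and the between-individual null-model
  correction for the spatial constraint on short-distance migrants.
- **Synthetic data**: a generator with known ground truth (sites, dates,
  routes, variance components) so the entire pipeline is testable offline.

## Worked example

Simulate a small population with known truth and run the full pipeline:

```r
library(migvar)

cfg <- population_config(n_individuals = 12, years_per_individual = c(2, 3),
                         migration_distance_range_km = c(300, 3000), seed = 7)
gen <- generate_population(cfg)
res <- run_pipeline(gen$fixes, cfg$colonies,
                    run_config(n_perm = 1000, n_boot = 100, seed = 7))
res
#> pipeline result: 12 individuals, 32 seasons
#>   non-breeding overlap: median within 0.948, between 0.566 (p = 0.01099)
#>   R(colony_departure) = 0.687
#>   R(winter_arrival) = 0.997
#>   R(winter_departure) = 0.796
#>   R(colony_arrival) = 0.769
```

Individuals reuse their own non-breeding range across years (median
self-overlap 0.948 out of a 0.95 maximum) far more than distance-matched
pairs of different individuals do (0.566), and the randomization test says
that contrast is unlikely under exchangeable labels (p = 0.011 at 1,000
permutations). Timing repeatabilities recover the generative among- vs
within-individual variance structure (R_true = 0.8 here; winter arrival is
higher because short-distance direct migrants arrive a fixed travel time
after departing). Each summary component is available in full:

```r
res$stats$overlap_distance
#> value = 0.9489 + -8.747e-07 * distance_km; F(1,10) = 1.793, p = 0.2102 (n = 12)
res$stats$repeatability$colony_departure
#> repeatability R = 0.687 (s_a2 = 22.648, s_eps2 = 10.337, colony var = 0.000) [singular fit]
#>   95% CI [0.271, 0.881] (100 bootstraps)
```

Passing `out_dir =` to `run_pipeline()` writes the season records,
per-individual metrics, pair tables, repeatability tables, route GeoJSON
and a run manifest (all delimited text / JSON); re-running with the same
inputs and seed reproduces them exactly.

Real data enter through `read_tracks()` (comma- or tab-separated
`individual_id, timestamp, lon, lat`, with column renaming) in place of the
generator output.

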