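---
title: "Quantifying individual variation in migratory behaviour from GPS tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying individual variation in migratory behaviour from GPS tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migvar)
```

## The problem

Seasonal migrants such as lesser black-backed gulls differ enormously in
where and when they spend the non-breeding season: individuals from one
colony may winter 50 km away or on another continent. A central question in
movement ecology is how much of the population-level variation in migratory
behaviour is *between* individuals (consistent individual strategies, driven
by learned or inherited information) versus *within* individuals across
years (plastic adjustment to current conditions), and whether the balance
shifts with migration distance.

`migvar` implements a complete pipeline for answering that question from
multi-year GPS tracking data: utilization-distribution overlap across
years, fine-scale winter site fidelity, mean migration routes with a route
variation statistic, migration phenology, repeatability from mixed-model
variance components, distance-constrained between-individual comparisons
with a randomization null, and a between-individual null-model correction
for the spatial constraint on short-distance migrants. A synthetic track
generator with fully known ground truth makes every stage testable without
access to field data.

## Space use

**Seasonal utilization distributions.** Fixes between colony departure and
colony arrival are subsampled to a 12-h interval (keeping, in each bin
anchored at the season's first fix, the fix nearest the bin centre — a
symmetric rule that does not bias timing) and projected to an equal-area
azimuthal (spherical Lambert) projection. The UD is a fixed bivariate
normal kernel estimate on a 10-km grid with bandwidth $h$ = 100 km,
deliberately coarse so that "same region" rather than "same roost" drives
the seasonal comparison. Cell masses are evaluated at the cell centre times
the cell area; with $h$ ten times the cell size this centre approximation
errs by less than $10^{-4}$ against the exact Gaussian integral (an
`exact = TRUE` path exists and is oracle-checked in the tests). Grids are
snapped to a global lattice anchored at the projection origin, so any two
UDs with the same cell size can be compared cell-by-cell without mass
redistribution.

**Core areas and the wintering area.** Core areas are the connected
components of the 50% isopleth: cells are ranked by mass (ties broken by
cell index) and accumulated until half the mass is enclosed. The wintering
area is the core area with the most dwell time between 1 December and
31 March (UTC dates; the analysis operationalises "December–March" as this
inclusive window), with exact dwell ties going to the core area farther
from the colony. Dwell is counted in 12-h fixes (0.5 day units), matching
the UD's data basis. When one year's wintering polygon overlaps two or more
fragments of another year's 50% set, the fragments are unioned, iterated to
a fixed point so the grouping is symmetric and idempotent.

A consequence of ranking equal-shape kernels by mass is that a secondary
cluster enters the 50% set only when it holds somewhat more than a quarter
of the season's mass; prolonged stopovers clear this comfortably, short
travel rests do not — which is exactly the intended distinction between a
stopover core area and en-route resting.

**Overlap.** Similarity of two UDs is Bhattacharyya's affinity,
$BA = \sum_{cells} \sqrt{p_i q_i}$. "95% UD" means masses outside the 95%
isopleth are zeroed and *not* renormalized, so the highest attainable
overlap is 0.95; this convention is pinned by a dedicated acceptance check.
Intra-individual overlap is the mean BA over all unordered season pairs of
an individual.

**Winter site fidelity.** Within the wintering window all fixes are used at
full rate, and a biased-random-bridge UD is built on a 500-m grid: every
step no longer than 3 h and no shorter than 20 m contributes kernels at 10
positions interpolated along the step, with variance
$h_{min}^2 + 4 D T p(1-p)$ at relative time $p$ ($h_{min}$ = 150 m); steps
failing either threshold contribute endpoint kernels at $h_{min}$. The
fixed per-step kernel budget (10 positions, weight 1/10) matches kernel
mass across steps of unequal duration and is checked against a
finer-discretization oracle in the tests. The diffusion coefficient $D$ is
estimated from the data by a robust plug-in-style estimator:
$\hat D = \mathrm{median}(L^2 / 4T) / \ln 2$ over eligible steps. For
two-dimensional Brownian motion $L^2/4DT$ is unit-mean exponential with
median $\ln 2$, so the correction makes the median estimator consistent
while retaining robustness to non-Brownian bursts; it is an approximation
to (not a re-implementation of) the plug-in estimators in the movement
literature. In the $D \to 0$ limit with sub-threshold movement the bridge
estimator collapses exactly to the fixed kernel at $h_{min}$, which the
test suite asserts at $10^{-6}$; for moving steps the interpolated kernel
centres lie between fixes, so the limit statement applies to residence-like
data. Site fidelity is then the mean pairwise BA of 95%-truncated winter
UDs.

## Routes

Migration legs run from colony departure to winter arrival (autumn) and
winter departure to colony arrival (spring), at full fix rate. Contiguous
stopover visits are collapsed to a single point at the stopover centroid,
so legs contain only migratory flight; legs holding a gap longer than 24 h
while outside core areas are dropped. The *mean route* is a sequence of 500
points minimizing the squared distance to nearest-neighbour locations on
the yearly legs: initialized as the arc-length-uniform resampling of the
leg-wise coordinate average, then refined by sweeps that move each point to
the centroid of its nearest locations (continuous point-to-segment
matching, robust to uneven fix spacing) and re-space the points uniformly
by arc length. A sweep that increases the objective is rejected and
iteration stops; convergence is declared when the largest point
displacement falls below 1 km (at most 200 sweeps, with a warning flag on
non-convergence). Per mean-route point, the variance is the mean squared
distance (km²) to each leg's nearest location; the headline *route
variation* is the square root of the mean per-point variance, carrying km
units (the mean variance in km² is also exported, since either reading is
defensible). The metric is homogeneous of degree one and rigid-motion
invariant, and identical legs give exactly zero; parallel legs offset
$\pm d$ give exactly $d$.

## Statistics

**Pairing.** Between-individual comparisons use all unordered pairs whose
colonies and wintering centroids are both within 250 km, with one season
per individual selected uniformly at random (deterministic given the run
seed); paired seasons need not share years.

**Randomization test.** The observed statistic is the difference of group
medians (between minus within, oriented so larger means more
between-individual variation). Group labels are shuffled 10,000 times
preserving sizes, and the one-sided add-one p-value
$(1 + \#\{\Delta_{perm} \ge \Delta_{obs}\})/(n_{perm}+1)$ is reported — never
exactly zero, and exact against full enumeration on small problems. Under
exchangeability its rejection rate at $\alpha = 0.05$ is verified to be
$0.05 \pm 0.01$ over 2,000 simulated data sets.

**Repeatability.** For each timing trait (colony departure, winter arrival,
winter departure, colony arrival, expressed as days since 1 July of the
season's starting year so that dates are comparable across years), a REML
linear mixed model with migration distance as a fixed effect and colony and
individual as random intercepts partitions the variance;
$R = s_a^2/(s_a^2+s_\varepsilon^2)$. Year is deliberately *not* a random
effect, so year-to-year plasticity lands in the residual. For winter
arrival the distance fixed effect is dropped (exposed as a flag) to aid
convergence. Confidence intervals come from 1,000 parametric bootstraps
(simulate-and-refit, deterministic given the seed; refit failures are
skipped and counted). Individual-level repeatability substitutes individual
$i$'s residual variance: $s_i^2 = \sum res_i^2 / (n_i - 1)$ (the
denominator is a package choice; with fewer than two observations the
individual is skipped), $R_i = s_a^2/(s_a^2+s_i^2)$.

**Distance models and the null-model correction.** Variation metrics are
regressed on the per-individual median migration distance by ordinary least
squares, compared against the intercept-only model by the F test (the
reported form) and the likelihood-ratio test (equivalent for nested
Gaussian models; both are returned). Because short-distance migrants are
spatially constrained, the between-pair metric regressed on pair mean
distance serves as a null model: its prediction is subtracted from each
individual's observed value, and the corrected values are regressed on
distance again. Individuals whose yearly wintering polygons are not all
pairwise-overlapping ("switchers") are excluded from distance regressions,
individual repeatability and the pairwise metrics, but retained in
population repeatability of timing.

## The synthetic population generator

`population_config()` / `generate_population()` simulate the statistical
structure the analysis assumes, with known truth:

- **Sites and routes.** Each individual gets a colony, a migration distance
  (default uniform on 50–4,600 km) and a bearing in a configurable sector
  (default 190–215°, concentrating winter sites along a corridor so the
  250-km pairing constraint is satisfiable; widen the sector to make it
  unsatisfiable). Individuals migrating at least 1,000 km maintain a
  stopover site (probability 0.7) placed part-way along the great circle,
  displaced laterally by an individual offset (SD 30 km); yearly routes add
  a smooth lateral jitter (SD 10 km). Offsets are clamped to 8% of the leg
  so realized flight speeds stay within 20–80 km/h.
- **Timing.** Individual mean event days are normal around population means
  (defaults: departure late July, winter arrival late October, winter
  departure mid March, colony arrival late March) with among-individual SD
  `sigma_among_days`; yearly dates are normal around the individual mean
  with `sigma_within_days`, rounded to days and scheduled at midday UTC,
  with ordering enforced. The implied timing repeatability is
  $R_{true} = \sigma_a^2/(\sigma_a^2+\sigma_w^2)$. Direct migrants (no
  stopover) arrive at the winter site a fixed short travel time after
  departure, since there is nowhere to absorb a long outbound window.
- **Movement.** Residence is a stationary AR(1) walk around the site
  centroid (SD 3 km, hourly); legs fly the great circle at a constant
  per-leg speed drawn from 30–70 km/h. Short travel rests (under the 21-day
  stopover scale) absorb schedule slack without creating core areas.
- **Gaps.** `inject_gaps()` deletes fix runs with configurable probability,
  duration and placement window, deterministically per seed.

Scheduling transitions at midday means the measured dates (polygon entry
and exit are crossed one-to-three hours around the scheduled time at
flight speed) never fall on the wrong calendar day, which is why phenology
recovery on gap-free tracks is exact at the trait's daily resolution. What
the generator does *not* emulate: wind and weather, foraging excursions
during migration, solar-charging duty cycles, device failure clustering,
or behaviour-dependent fix quality. Passing the recovery tests therefore
shows the pipeline is correct under the assumed statistical structure, not
that it is robust to every artefact of real telemetry.

Two generator consequences worth knowing: for migrations shorter than
about 300 km the colony sits inside the 100-km-bandwidth winter polygon,
so winter arrival is measured essentially at departure (true of any data
at this bandwidth, not just synthetic); and a secondary cluster needs more
than roughly a quarter of the seasonal mass to register as a core area, so
stopover dwell must be prolonged, as it is with the default timing means.

## Problem sizes and numerical choices

The test suite validates repeatability recovery on 80 individuals x 3
years (hourly fixes, distances 1,000–3,000 km, all with stopovers) at
generative $R_{true}$ of 0.9 and 0.5, requiring $|\hat R - R_{true}| \le
0.1$ per trait; day-rounding of dates adds about 0.08 days² to the
within-individual variance, a negligible attenuation at these scales.
Kernel UDs are checked to $10^{-10}$ against a brute-force mixture oracle
on a 50x50 grid; route objectives to $10^{-9}$ against an independent
point-to-segment oracle. The randomization size check uses 499
permutations per data set over 2,000 Gaussian null data sets. Grid
comparisons are extent-insensitive because truncation happens before
lattice embedding and out-of-extent cells carry no mass.

Degenerate inputs are handled explicitly: fewer than 5 fixes for a kernel
UD, an empty winter window, no eligible steps for diffusion estimation, no
December–March residence, a season never entering the winter polygon, zero
distance variance in a regression, and singular mixed-model fits (flagged,
with $R$ still computed from the returned components) are all errors or
flags, not silent results.

## Known limitations

- The plug-in diffusion estimator is a documented approximation; absolute
  winter-fidelity values (though not their ordering) shift slightly with
  the interpolation density and $D$.
- The mean-route algorithm is the minimal procedure satisfying
  "minimizes the distance to nearest-neighbour locations": other published
  variants differ in initialization and stopping rules, so per-individual
  route variation should be compared within one implementation.
- BA between UDs is sensitive at the $10^{-3}$ level to grid extent
  conventions; the shared-lattice design makes the package self-consistent
  but not bit-identical to other software.
- The season splitter requires sustained (default 7-day) colony presence to
  close a season; brief mid-season visits to the colony radius are treated
  as excursions, a documented convention rather than an inference from
  data.
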