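---
title: "Methods: standardized ratios, distance-band risk analysis and disease mapping"
author: "areaepi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: standardized ratios, distance-band risk analysis and disease mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(areaepi)
```

`areaepi` computes the three standard products of small-area
environmental epidemiology from aggregated registry data: standardized
rates and ratios, risk analysis in distance bands around putative
pollution sources, and smoothed disease maps with exceedance
probabilities. This vignette is the package's account of the underlying
statistics, the tunable parameters, the numerical choices, and what the
synthetic-data tests do and do not establish about behaviour on real
data.

## Data model

All health inputs are stratified tables: one row per cell of
area × sex × age band × calendar year (× optional covariate quintile),
holding an event count (`stratCounts`) or person-years at risk
(`stratPopulation`). The age-band list is declared at load time rather
than hard-coded — registries differ, and nothing in the methods depends
on a particular resolution; the fixtures use eighteen 5-year bands
(0–4 … 85+) as a conventional default. Validation enforces unique
stratum keys, known bands, and non-negative (integer, for counts)
values, reporting offending file lines. Latency between exposure and
outcome is handled by the caller shifting the year filter when selecting
events; a dedicated latency mechanism would only re-express that shift.

Disease codes are declared as `codeFilter` sets (ICD-9, ICD-10 or
user-defined), with inclusive ranges expanded deterministically
(`expandCodeFilter`); expansion is idempotent and order-invariant, and
an ICD-10 range must stay within one chapter letter.

Intercensal denominators come from `interpolatePopulation`: cellwise
linear interpolation between census tables, exact at census years,
refusing extrapolation beyond the census hull unless explicitly allowed.
Linear interpolation is the defensible minimum when only decennial
censuses exist; it cannot capture non-linear population change, which is
a recognised source of uncertainty in long study periods.

Area-level covariates are cut into quintiles (`assignQuintiles`) at the
20/40/60/80th percentiles (type-7 quantiles); an area exactly on a
boundary takes the *lower* quintile. The tie rule is a genuine open
choice — nothing in the methods forces a direction — so it is fixed,
documented and tested; with all values equal every area lands in
quintile 1. The `carstairsIndex` builder sums z-scores (unweighted
area-level mean/SD, the index's conventional construction) of male
unemployment, lack of car access, low social class and overcrowding;
a zero-variance component carries no ranking information and is dropped
with a warning rather than poisoning the sum with 0/0.

## Standardization

Indirect standardization projects reference stratum rates onto the study
population: $E = \sum_s n_s r_s$ (`expectedCount`), additive over
disjoint area sets so band totals decompose exactly by area. The ratio
$O/E$ (`indirectRatio`) carries a 95% interval from Byar's cube-root
approximation to the exact Poisson limits; the exact chi-square
inversion is available via `method = "exact_poisson"`. Byar is the
default because it reproduces routine published tables to their printed
precision and agrees with the exact limits to well under 0.01 on the
ratio scale for counts above ~20 (a property the test suite sweeps). At
$O = 0$ the ratio and lower limit are 0 and the upper limit is the
zero-count Byar bound. When a study region is compared against a
reference that contains it (a state against itself), the reference rates
include the study area by default; `referenceRates` takes
`exclude_counts`/`exclude_pop` to remove the study contribution first.

Directly standardized rates (`directRate`) apply study stratum rates to
standard-population weights, $rate = per \times \sum_s w_s\, o_s/n_s$,
with the Fay–Feuer gamma interval — the standard choice for weighted
Poisson sums, which behaves correctly at small counts where the normal
approximation fails. Reports round to 2 decimals (half-even); internal
values are never rounded.

Covariate adjustment is purely structural: adding `quintile` to the
stratification refines both the reference rates and the expected counts.
A covariate constant across areas therefore changes nothing — the
adjusted and unadjusted expected counts coincide exactly, which the
suite asserts.

## Geography and distance bands

No geospatial stack is assumed: the package carries its own planar
geometry (shoelace area/centroid, point-to-segment distance, even-odd
point-in-polygon) and reads/writes GeoJSON. All distances are computed
in a projected metric CRS; coordinates that look geographic are refused
unless the caller either declares a planar CRS or requests the built-in
local equirectangular projection (`projectLonLat`) — buffering in
degrees is meaningless. Geometric centroids are always recomputed from
the polygons; population-weighted centroids are supplied as data, since
they cannot be derived from boundaries alone.

Distance bands are half-open rings $[d_{k-1}, d_k)$ of nearest-source
distance, so with multiple sources the bands are automatically disjoint
unions of buffer rings minus inner buffers. A centroid exactly on a
break belongs to the *outer* band; the convention is arbitrary but must
be fixed for assignments to be reproducible. Area membership
(`selectAreas`) is by the chosen centroid; centroids beyond the
outermost break are unassigned and excluded from band analyses (they
remain in mapping analyses). The GeoJSON band-region export renders
per-source annuli for point sources as a visualisation aid; membership
is always computed from distances, never from rendered polygons.

Contiguity (`buildAdjacency`) is vertex-based after snapping to a
tolerance grid: queen = any shared vertex, rook = a shared edge. This is
exact for conforming layers (lattices, census geographies digitised with
shared borders); polygon layers whose common borders are digitised with
*different* vertices would need pre-snapping, a documented limitation.

## Band tests

Within bands, observed and expected counts aggregate over member areas
and `indirectRatio` supplies per-band SIRs. Both tests condition on the
overall ratio $\hat\theta = \sum O_k / \sum E_k$, the standard practice
for SMR heterogeneity, with no continuity correction:

* homogeneity: $X^2 = \sum_k (O_k - \hat\theta E_k)^2 / (\hat\theta
  E_k)$ on $K-1$ df;
* linear trend: the Poisson score test of slope zero in
  $O_k \sim \mathrm{Poisson}(E_k e^{\beta_0 + \beta_1 x_k})$, with
  $U = \sum x_k O_k - \hat\theta \sum x_k E_k$,
  $V = \hat\theta[\sum x_k^2 E_k - (\sum x_k E_k)^2/\sum E_k]$ and
  $z = U/\sqrt V$.

With two bands the two are the same test: $X^2 = z^2$ exactly, an
analytic identity the suite checks to $10^{-9}$. Band scores default to
ring midpoint distances in km; band rank is the common alternative
(nothing canonical fixes the scores, so they are a parameter). Bands
with zero expected count are dropped from both tests with a warning.
Simulation at $K = 3$, $E = (50, 100, 200)$, 5,000 null replicates puts
both tests' empirical size near the nominal 5% (the acceptance suite
requires [0.03, 0.07]), and under a monotone gradient
(1.5, 1.2, 1.0) the trend test is the more powerful, as it should be.

## Disease mapping

### Empirical Bayes (global-mean shrinkage)

`ebPoissonGamma` fits $O_i \sim \mathrm{Poisson}(E_i RR_i)$,
$RR_i \sim \mathrm{Gamma}(\alpha, \nu)$, maximizing the marginal
negative-binomial likelihood on $(\log\alpha, \log\nu)$ with L-BFGS-B
(tolerance $10^{-8}$ on the log-marginal; bounds $e^{\pm 18.4}$ keep the
optimizer off the boundary pathologies). Moment estimates initialize the
search: prior mean $\sum O/\sum E$, prior variance the expected-count
weighted SMR variance minus the Poisson component, floored at $10^{-4}$.
If the optimizer fails, the moment estimates are used and flagged. The
posterior mean $(O_i + \alpha)/(E_i + \nu)$ lies strictly between the
raw ratio and the prior mean (mediant inequality) — that is the precise
sense of "shrinkage toward the global mean", and the sense in which the
acceptance suite asserts it; the fitted prior mean and the crude overall
ratio differ only in the third decimal on realistic fields. Shrinkage
decreases with $E_i$ and vanishes in the large-$E$ limit. Areas with
$E_i \le 0$ are excluded and reported missing, never as risk 0. All
counts zero is degenerate (no overdispersion information) and is an
error.

### Full Bayes (local-mean shrinkage)

`bymFit` implements the convolution model
$\log RR_i = \mu + u_i + v_i$ with an intrinsic CAR prior on $u$ over
the adjacency graph, iid normal $v$, flat $\mu$, and
$\mathrm{Gamma}(0.5, 0.0005)$ hyperpriors on both precisions — the
conventional weakly-informative choice for log-relative-risk precisions
(the model's originators did not canonize hyperpriors; these are
configurable and flagged as a convention). Sampling is
Metropolis-within-Gibbs:

* random-walk Metropolis for $\mu$, each $u_i$ and each $v_i$; the
  $v_i$ (conditionally independent) update as one vectorised block, and
  the $u_i$ update in blocks given by a greedy colouring of the
  adjacency graph — areas of one colour are mutually non-adjacent, hence
  conditionally independent given the rest, so vectorising within a
  colour preserves detailed balance;
* conjugate Gibbs draws for $\tau_u$ (shape $a_u + (n - c)/2$ with $c$
  the number of connected components — the ICAR rank correction — and
  rate $b_u + \frac12\sum_{i\sim j}(u_i-u_j)^2$) and $\tau_v$;
* $u$ recentred to sum to zero per connected component after every
  sweep; with a single component the removed mean is absorbed into
  $\mu$, leaving all fitted risks untouched. Isolated areas take
  $u_i \equiv 0$ (unstructured smoothing only) with a warning.

Defaults are 11,000 sweeps, 1,000 burn-in, thinning 5 (2,000 retained
draws); random-walk scales adapt every 100 burn-in sweeps toward 30–50%
acceptance and are frozen afterwards, preserving the correct stationary
distribution. The seed is mandatory: identical seed and inputs give
bitwise-identical chains. Monte-Carlo standard errors use 20-batch
means.

Correctness of the sampler is checked two ways: swapping the Poisson
likelihood for a conjugate normal one (`family = "normal"`, fixed
precisions) makes the whole posterior Gaussian, and the chain's
per-area means and SDs must match the closed form computed by linear
algebra on the sum-to-zero subspace; and on a flat field
($O_i = E_i = 200$) posterior mean risks stay within (0.93, 1.07) with
exceedance probabilities in (0.2, 0.8) everywhere.

### Exceedance and classification

`exceedanceProb` is the fraction of retained draws with
$RR_i > 1$ (at least 100 draws required for a stable tail fraction);
`classifyRisk` applies the 0.8/0.2 rule: *elevated* iff the posterior
mean exceeds 1 **and** exceedance exceeds 0.8 (an excess risk asserted
with 80% confidence), *lowered* symmetrically below 0.2, otherwise
*uncertain*. On a 10×10 lattice with a 3×3 block at true RR 3 and
$E = 50$ per area, the block's exceedance is essentially 1 and every
block cell classifies elevated. Individual *null* areas can still reach
high exceedance by Poisson fluctuation — at $E = 50$ a chance raw SMR of
1.3 legitimately concentrates posterior mass above 1 — so the far field
is equivocal in central tendency (median exceedance below 0.6), not
area-by-area; absorbing that sporadic flagging is exactly what the 0.8
threshold is for.

EB and FB differ as intended: on a spatially correlated truth (ICAR
draw), the full-Bayes posterior means rank-correlate with the
neighbourhood-smoothed truth better than the EB estimates do, because
the convolution model borrows strength locally while the Poisson-gamma
model shrinks every area toward one global mean.

## The synthetic-data generator

`simulateCounts` draws, per stratum cell,
$\mathrm{events} \sim \mathrm{Poisson}(\mathrm{person\_years} \times
\mathrm{rate} \times RR_{\mathrm{area}})$ over a lattice geography, with
baseline rates rising log-linearly with age from $5\times10^{-6}$
per person-year at a 0.25 log increment per 5-year band and a 1.3 male
excess — the shape and order of magnitude of adult cancer incidence —
and log-normal person-years across areas (median 300 per cell, log-SD
0.5), mimicking the skew of ward-level denominators and exercising
sparse-count shrinkage. Truth surfaces: constant, banded-by-distance,
rectangular block anomaly, or a spatially correlated field (ICAR draw at
precision 10, exponentiated and mean-normalized to 1 — strong enough
correlation to separate local from global smoothing detectably). The
returned reference rates *are* the baselines, so expected counts close
the books exactly ($E_i = \sum \mathrm{py} \times \mathrm{rate}$) and
the truth is recoverable as $E[O_i] = E_i RR_i$.

What the generator does **not** emulate — and hence what passing tests
do not establish — includes: migration and population turnover,
boundary changes over time, registration and ascertainment artefacts,
irregular real polygon geometries, exposure misclassification, and any
systematic relation between deprivation and risk. Tests on this
generator validate the *computations*; they cannot validate the
epidemiological assumptions a real study must defend.

## Problem sizes and test budget

The shipped checks run at desk scale by choice: 5,000 replicates for
test calibration, 500 areas for EB recovery, 10×10 lattices with
5,500-sweep chains for the BYM behaviour checks and 26,000 sweeps for
the conjugate-harness moment comparison. These sizes give Monte-Carlo
error comfortably inside the asserted tolerances while keeping the whole
suite under a minute of compute.

## Known limitations

* Contiguity requires conforming polygon layers (shared borders with
  shared vertices after snapping).
* Band-region GeoJSON rendering covers point sources; line/polygon
  sources participate fully in distance computation but are not
  rendered as annuli.
* With multiple connected components the per-component recentring of
  $u$ cannot be absorbed into the single intercept; this is the
  standard practical treatment of disconnected ICAR graphs, at the cost
  of a slight approximation in the component-level risk levels.
* Linear intercensal interpolation, centroid-based area selection and
  the modifiable areal unit problem all shape results in ways no
  computation can remove; they are properties of the study design.
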