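---
title: "From gridded air-quality surfaces to census-unit population exposures: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From gridded air-quality surfaces to census-unit population exposures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridshed)
```

## The problem

Model-fused air-quality products (e.g. Bayesian fusions of CMAQ output with
monitor data) arrive as daily gridded surfaces: one concentration $P_i$ and
one standard error $\sigma_i$ per grid cell per day, on a 36 km or 12 km
lattice. Health and socioeconomic data, by contrast, live on census geography
— block groups (BG), tracts, counties, states. `gridshed` bridges the two:
it allocates the gridded concentrations to block groups, converts those to
*population* exposures for coarser census units, summarises them against the
daily NAAQS, and quantifies how well the block-group estimates track ground
monitors.

The block group is the base unit because it is the finest census geography
with annually available population (600–3,000 residents, optimally about
1,500).

## The model

**Block-group concentration.** Each BG is represented by its centroid. The
four nearest grid centroids (geodesic distance) receive inverse-squared
-distance weights

$$w_i = \frac{1/d_i^2}{\sum_{j=1}^{4} 1/d_j^2},$$

and the BG daily concentration and its standard error are

$$\mu = \sum_{i=1}^{4} w_i P_i, \qquad
  \delta = \sqrt{\sum_{i=1}^{4} w_i^2 \sigma_i^2}.$$

$\mu$ is a convex combination of neighbour values; $\delta$ assumes the four
cells' errors are independent (a known simplification that tends to
understate $\delta$, since neighbouring cells of a smoothed surface are
positively correlated).

**Population exposure.** For a census unit with member BGs
$i = 1, \dots, n$, population shares $a_i = \mathrm{pop}_i / \sum_j
\mathrm{pop}_j$ give

$$PE = \sum_{i=1}^{n} a_i \mu_i, \qquad
  \psi = \sqrt{\sum_{i=1}^{n} a_i^2 \delta_i^2}.$$

Two deliberate repairs of ambiguous source notation are baked in and worth
stating plainly: the weight denominator runs over all $n$ members (a
four-member denominator would not normalise), and $\psi$ is defined as the
*square root* of the weighted variance sum, for dimensional consistency with
its role as a standard error. Because the weights are population shares,
aggregation is associative: BG→state→national equals BG→national exactly, a
property the test suite checks by computing both paths independently.

A unit with zero total population has no defined exposure ("no population,
no exposure") and is an error; individual zero-population members simply
carry weight zero.

## Geodesy

Distances are Vincenty inverse solutions on WGS84
($a = 6378137$ m, $f = 1/298.257223563$), in kilometres. The ellipsoid is a
documented choice — the original SAS GEODIST implementation does not state
one — but it is immaterial downstream: IDW weights are invariant to any
rescaling of distance, so even a spherical approximation would change
nothing except reported distances. Iteration stops when the auxiliary
longitude update falls below $10^{-12}$ rad (cap 200 iterations; reachable
only near antipodal pairs, which raise an error). Agreement with an
independent geodesic implementation (Karney's algorithm via pyproj, frozen
as a text fixture of 1,000 random continental-US pairs) is required to be
within 1 m; observed agreement is sub-micrometre.

**Zero distance.** The weight formula is undefined at $d = 0$. We take its
continuous limit: coincident cell(s) absorb all weight, split equally if
several coincide. Four distinct cells all at distance zero indicates a
degenerate grid and errors.

**Ties.** Neighbour selection sorts by (distance, cell id) so equidistant
candidates resolve deterministically to the lexicographically smallest ids.

**Search routes.** Neighbour sets are computed once per BG (grid geometry is
time-invariant) by either brute force or an equirectangular prefilter with a
10% safety margin followed by exact geodesic ranking. The two routes must
agree exactly; the acceptance suite checks 100 random configurations.

## Summaries

* **Day-rank percentiles.** The "98th percentile of a year of daily
  exposures" is interpreted as a day rank: $k = \max(1,
  \mathrm{round}(p \cdot D))$ half-away-from-zero, returning the $k$-th
  highest day. For $D = 365$: $p = 0.02 \Rightarrow k = 7$;
  $p = 0.10 \Rightarrow k = 37$ (36.5 rounds up — the common gloss "about 35
  days" is arithmetically inconsistent, so the package follows the
  arithmetic and always reports the applied $k$ alongside the value).
* **Exceedance days** use *strict* inequality against the daily standard
  (35 µg/m³ PM2.5, 75 ppb ozone); the convention is configurable because
  sources rarely state ≥ vs >.
* **Map classes.** Five classes whose second-highest cut equals the standard
  $t$ and the rest sit at width-$w$ steps: breaks $(t-2w,\, t-w,\, t,\,
  t+w)$, left-open/right-closed, i.e. 15/25/35/45 for PM2.5 and 55/65/75/85
  for ozone at the defaults.
* **Population at risk** at a level is the summed population of member BGs
  whose exceedance-day count meets the minimum-days criterion (7/14/28 by
  default), with the percentage relative to unit population. Exceedance is
  counted on BG concentrations $\mu$, not on aggregated $PE$.

## Validation

Stations are assigned to BGs by an input column (point-in-polygon against BG
boundaries is out of scope; any GIS can produce the assignment). Pairs are
(station, date) combinations where both an observation and a BG estimate
exist; BGs with two monitors contribute two pairs per date. Metrics:

* **MAD** — mean absolute deviation $\overline{|\hat y - y|}$;
* **R** — *pooled* Pearson correlation over all pairs (not a mean of
  per-station correlations; pooling matches the convention of reporting one
  N across all observations), undefined and reported missing for constant
  columns;
* **absolute-deviation distribution** — min, 5th, 10th, median, 90th, 95th
  percentiles and max, using linear interpolation between order statistics
  (R's type-7 rule) as the single documented quantile convention.

Reports can be stratified by year, meteorological season (DJF/MAM/JJA/SON —
the source does not define its season split, so the standard meteorological
quarters are used) and an urban/rural flag.

## The synthetic world

Real inputs (EPA-fused surfaces, census geography and populations, AQS
monitors) are not publicly deposited, so the package carries a fully
deterministic generator whose defaults *are* the stated world of the tests:

* **Grid**: a regular lattice at 36 km nominal spacing (12 km available),
  converted to degrees at the origin latitude.
* **Field**: baseline 13 units (the order of a national annual PM2.5 mean)
  + seasonal sinusoid (amplitude 4) + a few smooth Gaussian spatial bumps
  (height ≤ 8, scale 80 km) + AR(1) day-to-day noise
  ($\phi = 0.6$, innovation sd 2). Standard errors are drawn strictly
  positive as $0.2 + |N(0,1)|$.
* **Truth** excludes the AR(1) term, so in recovery tests the station noise
  sd is the only stochastic gap between estimates and observations — a clean
  analytic target: the mean absolute value of $N(0, s)$ noise is
  $s\sqrt{2/\pi}$ (half-normal mean).
* **Block groups**: centroids uniform over the lattice box; GEOIDs
  constructed to honour a configurable state/county/tract nesting;
  populations drawn from a Beta(3, 5) scaled to [600, 3000], whose mean
  lands on the census optimum of 1,500.
* **Stations**: 25% of BGs host one monitor and 5% two (real BGs host 0–2);
  observations are BG truth + iid Normal noise.

Each component consumes its own seed derived from the global one, so adding
stations never perturbs the field. What the generator does *not* emulate:
emission/meteorology physics, spatially correlated standard-error fields,
coastlines or irregular census geography, population mobility. A green test
therefore establishes the correctness of the *pipeline arithmetic and its
invariants*, not the realism of any exposure surface.

## Numerical choices

* Weights must sum to 1 within $10^{-12}$; estimates are checked convex.
* Aggregation consistency (direct vs chained) is asserted at $10^{-9}$
  relative — pure floating-point headroom, as the algebra is exact.
* The MAD recovery criterion allows 10% of $s\sqrt{2/\pi}$ after adding the
  separately measured zero-noise interpolation bias (about 0.12 units at the
  default configuration, against a target of 2.39).
* GEOIDs are zero-padded strings end to end (state "04" must survive I/O);
  dates are ISO-8601 strings; CSV output is full double precision so reruns
  are byte-identical.
* All randomness lives in the generator; analysis stages take no seed.

## Limitations

BG centroids stand in for whole BG areas; independence is assumed across
grid cells and across BGs, understating $\delta$ and $\psi$; no daily
population mobility; 36 km and 12 km surfaces are never mixed within a run
(which surface a region uses is run-level configuration). Reproduction of
the source study's published validation tables and population-at-risk counts
is out of scope for lack of deposited data — the acceptance suite instead
pins the self-contained printed constants and the pipeline's structural
properties.
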