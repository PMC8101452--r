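---
title: "Bootstrap Mahalanobis climate niches and ecosystem-service change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bootstrap Mahalanobis climate niches and ecosystem-service change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichecast)
```

## The modelling problem

Many species of conservation and livelihood interest are documented only by
presence records scattered across herbaria and observation databases: there
are no absences, no reliable sampling background, and sample sizes vary by
two orders of magnitude between species. `nichecast` models the
*fundamental* climate niche of such species — the set of climates that
could support them, irrespective of where dispersal or land use has
actually put them — and asks how much of a study region carries suitable
climate now and under future scenarios. Because the species are carriers of
ecosystem services, per-species answers are pooled into per-service change
distributions.

## Environmental space

The 19 bioclimatic variables are strongly collinear, so all climates are
first mapped into a PCA environmental space fitted on the current-climate
cells of the study area:

1. rainfall variables (default `BIO12`–`BIO19`) are `log1p`-transformed.
   `log1p` rather than `log` because precipitation layers can legitimately
   contain zeros (driest-month or driest-quarter totals);
2. every variable is z-scored over the valid study-area cells (the study
   mask, not the full raster, defines the fitting population);
3. the correlation matrix of the transformed variables is
   eigen-decomposed (denominator *n* − 1) and the first *k* = 3 loading
   columns are retained. Variance fractions are reported for all 19
   components; each loading column's sign is chosen so its
   largest-absolute entry is positive, which makes scores reproducible
   across eigen-solvers.

Future stacks are projected with the *frozen* current-climate transform —
same log set, centers, scales and loadings — so that "the climate moved"
is expressed as cells moving through a fixed space, not as the space
deforming. Scores extrapolate linearly outside the training range, which is
intended: warmed climates may exit it.

An optional diagnostic, `climate_skew_report()`, tabulates skewness and a
bimodality coefficient per variable on raw and log scales; it informs the
choice of `log_vars` but never gates the fit, since transform choice is a
judgement call that should stay visible.

## The niche model

With occurrences reduced to one record per climate cell, the cell scores of
a species are summarised by their mean `mu` and sample covariance `sigma`
(denominator *n* − 1). For a climate `x`,

\[ D^2 = (x - \mu)^\top \Sigma^{-1} (x - \mu), \qquad
   p = \Pr(\chi^2_k \ge D^2), \]

is the probability of being within the fundamental niche: exactly 1 at the
centroid, strictly decreasing along any ray leaving it, and defining nested
probability ellipsoids in which the *p* ≥ 0.9 contour is the smallest.
The upper-tail reading of "chi-square probability" is the only one
consistent with both properties. \(D^2\) is computed through a Cholesky
factorisation and triangular solve; an explicit-inverse implementation
exists only as a test oracle.

Sampling uncertainty is propagated with a classical bootstrap: `B`
with-replacement resamples of size *n* (default `B = 1000`), one fitted
ellipsoid each. A degenerate resample — possible when a species occupies
few distinct cells — is redrawn up to 100 times, then ridge-regularised by
adding \(10^{-8}\,\mathrm{tr}(\Sigma)/k\) to the diagonal with a logged
warning. Input point sets that are themselves degenerate are refused before
any resampling.

## Occurrence cleaning

`clean_occurrences()` applies, in order: a coordinate bounds filter;
removal of records on nodata cells or off the grid; an optional elevation
cross-check against a DEM (default tolerance 500 m, *flag-only* by default
because mismatches deserve inspection rather than silent deletion — set
`drop_on_elev_flag = TRUE` to drop; records without a label elevation are
never flagged); and deduplication to one record per species per climate
cell, keeping the first record in input order (a stable, reproducible
tie-break). Counts removed per rule are reported per species, and input
count = retained + removed + malformed is a tested invariant.

Cells are half-open boxes (left/top edges inclusive), and points exactly on
the grid's outer edge are assigned to the adjacent interior cell, so every
in-grid point belongs to exactly one cell.

Species retaining fewer than `min_n = 20` cells are excluded from
modelling. The threshold is configurable: curated datasets sometimes keep
species marginally below a nominal cut, so the criterion is a parameter,
not a constant.

## Projection, areas and scenarios

Each bootstrap ellipsoid is mapped over the grid as a probability surface,
and its potential-niche **area** is the sum of per-cell probabilities times
the cell area — a probability-weighted area that needs no arbitrary
binarisation threshold. Cells are treated as uniform equal-area units;
no latitude-dependent correction is applied.

Scenarios form a factorial of periods {2050, 2070} × RCPs
{2.6, 4.5, 6.0, 8.5}. For each bootstrap model and scenario one GCM is
drawn uniformly at random (all GCMs treated as equally credible), and the
draw is independent per (species, bootstrap, scenario) and logged so the
shared-draw variant could be added later. The design is *paired*: the same
bootstrap model produces its own current and future areas, so per-bootstrap
changes are exact differences, and a future identical to the present gives
changes that are exactly zero (same code path, same inputs — a tested
invariant).

## Service aggregation

Areas are converted to percentages of the study area and changes to
percentage points (pp). Per service and scenario the pooled distribution
concatenates the B bootstrap changes of every member species: pooling
weighs species *by membership*, so a level-1 pool's `n` counts
species-service memberships, not distinct species, and the level-1 pool is
exactly the multiset union of its level-2 children (a tested invariant).
An equal-weight variant would be a small change; membership weighting is
the default because a service provided by more species genuinely rests on
more distributions. Beanplots (mirrored densities with a raw-value strip,
a median bar and a zero reference line) summarise the pools; the exact
plotted values are always exported as CSV so figures are auditable.

## The synthetic study system

The generator exists so every stage can be tested against known truth:

* **Current climate** — a latent elevation field (smooth low-order cosine
  basis) drives temperature through a linear lapse (default 6.5 °C/km from
  a 27 °C base, 2500 m relief: a tropical-mountain setting); a latent
  moisture field drives log-normal precipitation (annual total ~1200 mm);
  extremes are built as positive offsets from `BIO1` so
  `BIO5 ≥ BIO1 ≥ BIO6` holds by construction; a configurable nodata
  fraction is masked identically across layers.
* **Futures** — per scenario a mean warming offset (defaults 1.0/1.4/1.3/2.0
  °C for 2050 and 1.0/1.8/2.2/3.7 °C for 2070 under RCP 2.6/4.5/6.0/8.5,
  following published ensemble-mean warming levels) plus a per-GCM smooth
  disagreement field (sd 0.4 °C), and a seasonality inflation factor ≥ 1
  multiplying `BIO4`/`BIO15`. The cosine-field disagreement is a stand-in
  for real GCM structure, chosen so futures differ spatially and not just
  by offset.
* **Virtual species** — cells sampled *without replacement* with weight
  equal to the species' within-niche probability, so generated records
  already satisfy the one-per-cell rule (duplicates exist only via an
  explicit corruption option for testing the cleaner).
* **Catalogue** — each species draws 1–4 distinct level-2 services from a
  19-service/4-class pool with count weights whose median is two services
  per species, the typical multiplicity in useful-plant catalogues.

All randomness flows from one root seed through named substreams
(`climate`, `gcm`, `species`, `catalogue`, `bootstrap/<species>`,
`scenario/<species>`), so stages are independently reproducible and
inserting one never perturbs another.

What the generator does **not** emulate: real spatial autocorrelation of
GCM disagreement, latitude-dependent cell areas, observation and sampling
bias, non-ellipsoidal (e.g. skewed or multimodal) niches, and
biotic/dispersal constraints. Passing tests therefore demonstrate that the
machinery is correct under the stated model, not that real niches are
multivariate normal.

## Numerical and design choices

* Covariance denominators are *n* − 1 throughout.
* \(D^2\) via Cholesky + solve; SPD is checked with a relative eigenvalue
  tolerance; ridge fallback only after 100 bootstrap redraws.
* Half-open cell membership; outer-edge points to interior cells;
  duplicate survivor = first in input order.
* Raster stacks are stored on disk as one plain CSV grid per layer plus a
  JSON sidecar (grid geometry, layer order, nodata): a text format with an
  exact round trip, readable anywhere.
* Derived substream seeds stay below \(2^{31}\) (exact double arithmetic
  modulo \(2^{31}-1\)).

## Problem sizes

The package's reference desk-scale configuration — used by its end-to-end
tests and by `scripts/acceptance.R` — is a 60 × 60 grid (5% nodata), 12
virtual species with 60–400 occurrences, B = 200 bootstraps and 2 periods
× 4 RCPs × 5 GCMs, which exercises every stage of the factorial design
while remaining a desk-sized computation. Statistical acceptance checks
(probability calibration, parameter recovery) use up to \(10^5\) draws and
B = 1000, matching the scale at which their tolerances are meaningful.

## Limitations

Potential niche area overestimates realised area: competition shrinks the
realised niche, and dispersal limits actual occupancy further; no land-use
masking is applied. The ellipsoid model is unimodal and symmetric by
construction. GCM credibility is treated as uniform. These are properties
of the method, stated here so that pooled declines are read as climate
*potential*, not occupancy forecasts.
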