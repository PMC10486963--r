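---
title: "Methods: spatiotemporal analysis of gridded breeding-pair censuses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatiotemporal analysis of gridded breeding-pair censuses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridcensus)
```

## The problem

National raptor censuses are often summarised on a coarse square grid:
every confirmed breeding territory is assigned to a 10 x 10 km cell, and
each census year yields a per-cell count of breeding pairs. Two questions
follow naturally. First, has the regional occupancy-abundance structure
changed between censuses, or is the population stable? Second, where are
the cells in which abundance aggregates (or fails to aggregate) relative
to the neighbourhood, and which habitat, food-availability, human-pressure
and heterospecific covariates separate those cells?

`gridcensus` implements the full chain: temporal-stability testing with
rank occupancy-abundance profiles, spatial-aggregation detection with
global and local Moran statistics, a covariate screen between aggregation
classes, and negative-binomial abundance models with trend-surface terms
and AICc model averaging. Only the cells occupied in at least one census
year enter the analysis (`filter_ever_present()`): cells never occupied
over the whole period say nothing about the species' distributional
structure and would dilute every statistic with structural zeros.

## Temporal stability: ROAPs and D*

A rank occupancy-abundance profile (ROAP) plots per-cell abundance
against the cell's relative rank: the most abundant cell gets rank 1, and
each rank is divided by the total number of ever-occupied cells, so the
X axis is bounded by (0, 1] and profiles from different years are
directly comparable. The profile summarises both occupancy (where the
curve hits zero) and the frequency distribution of abundances (the shape
of the descending limb) in one curve.

Two years are compared through the area under each profile (trapezoidal
rule along the ranked polyline). The comparison statistic is

D* = min(AUC_a, AUC_b) / max(AUC_a, AUC_b),

which is 1 when the areas coincide and decays towards 0 as the
distributions diverge. The area-ratio form is a design choice of this
package: "area under the curve" admits several comparison conventions
(differences, maximum vertical distances), and the ratio was chosen
because it is symmetric, scale-interpretable (a year with twice the
abundance everywhere gives exactly 0.5) and reproduces the qualitative
ordering expected when total abundances drift slowly. The statistic is
isolated behind `dstar()`, so an alternative functional form can be
substituted without touching the permutation machinery.

Significance comes from year-relabelling permutations
(`dstar_permutation_test()`). The default scheme relabels per cell: each
cell's observed counts are randomly reassigned to the year labels, which
preserves every cell's multiset of counts and exchanges only the year
assignment. A pooled scheme (all counts of both years pooled across cells
and split at random) is also provided, because the two readings of
"pooling the abundance data and randomly assigning a year" genuinely
differ; per-cell is the default since it respects cell identity. The
test is one-sided in the lower tail (small D* = divergence) with the
standard +1 permutation correction, so the smallest attainable p-value is
1/(1 + n_iter). The default is 999 iterations; 100 reproduces the coarser
historical granularity and anything below 19 cannot resolve alpha = 0.05
at all (the function warns).

## Spatial aggregation: Moran's I and LISA

Spatial weights (`build_weights()`) are built from inter-centroid
distances only; coordinates are planar kilometres and no CRS handling is
attempted, since nothing downstream needs more than distances. The
default is a binary band at 20 km — two lattice steps, the scale at which
short-distance autocorrelation is typically reported for this kind of
census — with inverse-distance weighting and row standardisation
available. Weights are *not* row-standardised by default, because the
exact additivity identity sum(I_i) = S0 * I used to validate the local
statistics holds in the unstandardised scaling.

Global Moran's I is tested by Monte-Carlo permutation (default 999
permutations, one-sided towards aggregation). The correlogram recomputes
the statistic on distance-band-restricted weights per lag (default bins
at multiples of the 10 km cell size), flagging empty bins rather than
inventing a statistic for them.

`local_moran()` computes the per-cell decomposition I_i and classifies
each cell into the Moran-scatterplot quadrant (HH, LL, HL, LH) from the
signs of its centred value and spatial lag. Per-cell significance uses
conditional permutation: the cell's own value is held fixed while the
remaining values are reassigned among the other cells, which is the
standard null for local indicators. No multiple-testing correction is
applied by default — the classification is descriptive, mirroring common
LISA practice — but `adjust = "fdr"` is exposed and the caveat matters:
at alpha = 0.05 roughly 5% of cells will be flagged by chance under a
homogeneous field. `classify_high_low()` merges significant HH and HL
cells into a "High" class (abundance above the neighbourhood) and
significant LL and LH cells into "Low"; everything else, including
islands (cells with no neighbour inside the band), is "NS". We require
LISA significance for class membership, not quadrant membership alone.

## The covariate screen

`compare_high_low()` runs one Kruskal-Wallis test (tie-corrected,
chi-square approximation) per covariate between High and Low cells and
compares each p-value against the Bonferroni threshold alpha/m, with m
the number of variables tested (16 for the standard set). The threshold
formulation is decision-equivalent to inflating p-values and keeps the
reported p-values interpretable. Group means with t-based 95% confidence
intervals are reported for description only. With the small class counts
this screen typically sees (tens of cells per class), the chi-square
approximation is adequate; the Kruskal-Wallis statistic itself comes from
`stats::kruskal.test`.

## Abundance models

The response is the per-cell count in the most recent census; predictors
are z-scored covariates, a mandatory temporal term (the standardized
counts of an earlier census, named `NP00`, `NP08`, ...), and
trend-surface terms: the nine non-constant monomials of total degree <= 3
in the standardized centroid coordinates (X, Y, X2, Y2, X3, Y3, XY, X2Y,
XY2). Coordinates are standardized *before* powers are taken, which keeps
the monomials numerically well-conditioned. Standardizing all predictors
does not affect AICc ranking but makes averaged coefficients comparable
across terms.

Models are negative-binomial GLMs with log link (variance
mu + mu^2/theta), fitted by alternating IRLS and univariate theta scoring
via `MASS::glm.nb`; a fixed theta can be supplied, and large fixed theta
recovers a Poisson fit (the package checks this limit to four decimals in
its test suite). The parameter count k includes theta, so an
intercept + 5 predictor model has df = 7 in the candidate tables — the
convention under which the published-style tables' df column is
consistent with their AICc values.

Candidates are enumerated exhaustively (`enumerate_models()`): every
subset of the covariate pool crossed with every subset of at most
`max_spatial_terms` (default 4) trend-surface terms, the temporal term
always present. The default covariate pool is the set of variables that
pass the High/Low screen. Ranking uses AICc; the averaging set is
delta AICc < 2 with weights renormalized inside the set. Both full-model
averaging (absent terms contribute zero — the default reported
coefficients) and conditional averaging are returned, together with
per-term importance (sum of Akaike weights). The deviance-explained
pseudo-R2 (1 - residual/null deviance) is the default goodness-of-fit
summary; McFadden and Nagelkerke flavours are provided since the
deviance-based convention is a choice, not a canon.

Non-converged candidates are excluded from selection with a warning
rather than silently ranked: an unconverged log-likelihood is not
comparable.

## The synthetic-census generator

Because real census data of this kind are typically not shareable, the
generator (`synth_config()`, `simulate_census()`) is a first-class module
that produces censuses with the statistical structure the analysis
assumes, under known ground truth:

* a 10 x 10 km lattice, by default 40 x 26 = 1040 cells, matching the
  roughly one thousand ever-occupied cells of a national census;
* a zero-mean Gaussian latent field with exponential covariance
  `sill * exp(-d/range_km)` (default sill 0.5, range 20 km — the simplest
  stationary decay consistent with a correlogram that loses significance
  after a couple of lattice steps);
* AR(1) coupling of the field across years with coefficient rho
  (default 0.9, strong territory persistence), stationary so every year
  has the same marginal variance;
* negative-binomial counts with mean
  `exp(beta0 + sum(beta_j z_j) + field)` and dispersion theta = 2,
  giving small overdispersed counts; the default intercept (-0.15)
  compensates the log-normal mean inflation of the field and covariate
  terms so the mean count per cell is about 1.3, the scale of ~1300
  pairs over ~1000 cells with per-cell maxima near 8;
* default effects: positive cattle, griffon-pair, feeding-station and
  wood-pasture coefficients (+0.3/+0.3/+0.2/+0.2 per covariate SD) and a
  negative wind-turbine coefficient (-0.3);
* covariates generated as smooth random surfaces (land covers through a
  probit squash to [0, 100], livestock and griffons as log-normal
  fields) or sparse Poisson point counts (turbines, feeding stations,
  landfills, poisonings), so the screen sees realistic contrast.

What the generator does *not* emulate: observation error and imperfect
detection, migratory or demographic dynamics, and territory placement at
sub-cell resolution. Tests passing on synthetic data therefore certify
the statistical machinery — calibration of the permutation tests,
recovery of known effects, correctness of the bookkeeping — not the
ecological fidelity of any particular census.

## Numerical choices and degenerate inputs

* Counts are integers; fractional abundances are rejected, not rounded.
* Missing covariate values are rejected at load; no imputation.
* Constant fields make Moran statistics undefined and raise errors;
  all-identical covariates degrade the rank test to H = 0, p = 1 with a
  degeneracy flag.
* The latent-field covariance gets a 1e-10 diagonal jitter before
  Cholesky; failure after jitter is reported, not papered over.
* Permutation p-values always use the +1 correction, so they are valid
  (never zero) at any iteration count.
* Ties in ROAP ranking keep input order; the area statistic is
  tie-order invariant, so this is purely presentational.
* Stage seeds in `run_pipeline()` are derived deterministically from the
  master seed and the stage name, so stages are reproducible in
  isolation and changing one stage's permutation count does not perturb
  another's draws.

## Problem sizes used by the test suite

The suite exercises the permutation calibrations at 500 replicates of
200-cell grids with 199 permutations, coefficient recovery at 100
replicates of 1000-cell censuses, and selection-structure recovery at 50
replicates of 1000-cell censuses with a 128-model candidate set per
replicate (covariate pool of five, trend-surface pool {Y, Y2}). These
sizes were chosen as the smallest at which the binomial bounds and
recovery rates are sharp enough to be meaningful.

## Known limitations

* The D* functional form is a documented package choice (area ratio);
  other conventions exist in the profile-comparison literature.
* LISA p-values are per-cell and uncorrected by default; class counts at
  alpha = 0.05 include an expected false-positive fraction.
* Exhaustive enumeration grows as 2^p; the `max_models` cap errors
  early rather than letting a dredge run away.
* The weights specification (style, band) materially affects local
  Moran classes; the 20 km binary default should be treated as a
  starting point and varied in sensitivity analyses.
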