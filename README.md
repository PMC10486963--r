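# gridcensus

Spatiotemporal analysis of breeding-pair censuses recorded on a square
(UTM-style) 10 × 10 km grid, as produced by national raptor monitoring
schemes: a few census years, roughly a thousand ever-occupied cells, small
overdispersed per-cell counts. The package answers two questions about such
data and ships a synthetic generator so the whole chain is testable without
access to any real census.

**Is the regional occupancy–abundance structure stable over time?**
Each year is summarised as a Rank Occupancy–Abundance Profile (ROAP): the
per-cell abundance plotted against relative rank *k/n*, with rank 1 for the
most abundant of the *n* ever-occupied cells. Two years are compared through
the areas under their profiles,

    D* = min(AUC_a, AUC_b) / max(AUC_a, AUC_b)  ∈ (0, 1],

with significance from year-relabelling permutations (per-cell relabelling
by default; pooled relabelling available).

**Where does abundance aggregate, and what covaries with it?**
Global Moran's *I* (distance-band weights, Monte-Carlo permutation p) and a
distance-lag correlogram establish spatial autocorrelation; local Moran
(LISA) with conditional permutation classifies cells into High–High,
Low–Low, High–Low, Low–High quadrants, merged into **High** (significant
HH ∪ HL) and **Low** (significant LL ∪ LH) aggregation classes. A
Kruskal–Wallis screen with Bonferroni correction compares 16 per-cell
covariates (land covers, livestock, landfills, feeding stations, wind
turbines, poisoning events, griffon-vulture pairs, …) between High and Low
cells. Finally, negative-binomial GLMs (log link, variance μ + μ²/θ) model
the most recent census from the screened covariates, a temporal term (the
standardized counts of an earlier census, `NP00`/`NP08`), and third-degree
trend-surface monomials of the standardized coordinates; candidates are
enumerated exhaustively, ranked by AICc, and averaged over the
ΔAICc < 2 set with renormalized Akaike weights.

## Worked example

```r
library(gridcensus)

s <- simulate_census(synth_config(seed = 42))   # 40 x 26 grid, 3 years
rep <- run_pipeline(s$census, s$covariates,
                    pipeline_config(max_spatial_terms = 2, seed = 1),
                    out_dir = "demo_out")
print(rep)
```

The generator drew 1227 / 1341 / 1434 pairs in the three years over 1040
cells (871 ever occupied). The report starts with the stability table —
for example

```
 year_a year_b d_star p_value stable abundance_change occupancy_change
   2008   2000  0.911   0.140   TRUE              114               18
   2018   2000  0.862   0.045  FALSE              207               12
   2018   2008  0.946   0.392   TRUE               93               -6
```

so only the 18-year comparison (abundance up 207 pairs, D\* = 0.862) shows
a detectable change at α = 0.05. The spatial stage finds strong aggregation,

```
Global Moran's I = 0.1668 (null expectation -0.0011, n = 871)
  Monte-Carlo p = 0.001 (999 permutations, greater)
```

and the LISA classification yields 23 High cells (mean 11.5 pairs/cell,
18.5 % of all pairs on 2300 km²) against 34 Low cells (mean 0.47). The
Kruskal–Wallis screen then flags SHEEP and COW (p < 0.003125 = 0.05/16) as
separating High from Low cells in this realisation — with only 23 + 34
cells the screen has limited power, and the true griffon effect just misses
the Bonferroni bar (p = 0.065). The model-selection stage ranks 184
candidates per temporal term; with the NP08 term the ΔAICc < 2 set is
`COW + NP08 + X + X2` and `SHEEP + COW + NP08 + X + X2`, whose averaged
coefficients (on the per-SD scale)

```
(Intercept)         COW        NP08           X          X2       SHEEP
   0.447500    0.223500    0.279700   -0.133500   -0.147300    0.006819
```

recover the planted positive cattle effect (truth 0.3 per SD) next to the
temporal persistence term. Every stage's table is also written under
`demo_out/` (CSV, a GeoJSON layer of the High/Low map, and a `manifest.json`
echoing all parameters and stage seeds).

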