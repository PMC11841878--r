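---
title: "Methods: presence-background habitat modelling from canopy surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presence-background habitat modelling from canopy surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopyhsm)
```

This vignette explains the science implemented in `canopyhsm`: the model
and its assumptions, the parameters that matter, what the synthetic
forest generator does and does not emulate, and the numerical and design
choices made where more than one defensible option existed.

## The problem

Old-forest nesting habitat — for the marbled murrelet, large-limbed
conifers 50 m and taller — is rare, patchy, and visible in
high-resolution canopy structure. Direct nest observations are scarce, so
occupancy evidence comes as polygons of *used* habitat rather than used
trees, while the landscape as a whole defines what is *available*. That
data situation calls for a two-sample presence-background design: model
the ratio of habitat conditions at used locations to conditions at a
large spatially balanced background sample, and map the result as a
habitat suitability index (HSI).

## From canopy surface to covariates

**Tree approximate objects.** `extract_taos()` marks a cell of the canopy
DSM as a tree top when its value is positive, at least `min_height`, and
no cell within `window_radius` (circular, default 2 m) is higher.
The window default is deliberately small: stump-sprouting redwoods can
carry leaders within a metre of each other, and a wide window would merge
them. Plateau ties are resolved deterministically — one TAO at the
plateau's centroid cell, row-major order breaking any remaining tie —
and neighbourhoods are clipped at the raster edge; the sampling stage's
20-m boundary exclusion is the downstream answer to edge bias.

**Moving-window statistics.** `tao_window_stat()` computes, for every
5-m grid cell, statistics of the TAOs within a circular window of given
area in acres (1 acre → 35.89 m radius, 5 acres → 80.25 m, from
πr² = area × 4046.8564224 m²). Conventions the mathematics does not fix,
stated explicitly: the distance test is inclusive (a TAO exactly on the
rim counts); densities are reported per acre whatever the window size;
standard deviations use the sample (n − 1) denominator and are 0 for
windows with fewer than two trees; min/mean/max of an empty window are
reported as 0; the cell's value is computed at its centre. The production
implementation scatters each TAO into its disc of reachable cells, which
is algebraically identical to the per-cell brute-force scan the tests use
as an oracle.

## Balanced sampling

`bas_points()` draws a balanced acceptance sample: the 2-D Halton
sequence (bases 2 and 3) with independent random integer index offsets
drawn uniformly from [0, 10^7) — the simplest published random-start
variant, with offsets logged in the sample's metadata — scaled to the
region's bounding box, keeping points that fall inside the region.
`label_samples()` marks a point *used* when it lies in a used polygon at
least 20 m from the boundary (inclusive at exactly 20 m); every point,
used or not, remains available, so the used sample is a subset of the
background — the two-sample design the model expects. Both entry points
for sample size are supported (a fixed n, or hectares per point via
`target_n_for_density()`), since a fixed total and a target density are
equivalent up to rounding.

## The maximum-entropy model

Features are linear, quadratic, product and hinge transforms of the raw
covariates. Linear terms are standardised against the *available* sample
(the background characterises the landscape, so feature geometry must not
drift with the used sample); quadratics and products are built from the
standardised values; hinges sit at `n_knots` (default 50) equally spaced
quantiles of the available distribution and are rescaled to [0, 1].
The per-feature L1 penalty is

λ_j = RM × base(class, n_used) × sd_used(f_j) / √n_used,

with the published per-class base constants interpolated by used-sample
size and RM the single tuning multiplier (default 2.0). A feature that is
constant over the used sample falls back to its available-sample spread
so its penalty cannot vanish by accident; a covariate constant everywhere
is dropped with a warning.

`fit_maxent()` maximises the penalized presence-background log-likelihood
(per-presence scale) by cyclic coordinate ascent: each coordinate takes a
proximal Newton step with soft-thresholding, guarded by step halving so
the objective never decreases — the monotone trace is checked in the
tests on every fit. Convergence is declared when a full sweep improves
the objective by less than `tol` (default 1e-5, relative); the update cap
(default 5000 single-feature updates) mirrors the fitting-iteration
budget conventional for this model family, and hitting it raises a
warning with diagnostics rather than an error, because near-separated
data — common on deliberately separable synthetic scenarios — legitimately
converges slowly in its largest coefficients while the fit is already
stable for ranking purposes.

Outputs follow the standard conventions: raw predictions
`exp(β'f − logZ)` sum to one over the fitting background; the scaled
logistic output is `HSI = r·c/(1 + r·c)` with `c = exp(H)·τ/(1 − τ)`,
`H` the background entropy and τ = 0.5 by default (exposed in
`fit_config()`), so the null model scores 0.5 everywhere; training gain
is the mean used log raw output plus `log n_available` minus the penalty,
zero for the null model; AIC is `2k − 2 lnL` with `k` the count of
nonzero coefficients — the niche-modelling convention, which also makes
replicate-average parameter counts (reported alongside per-replicate
integer counts) meaningful. The log-likelihood is defined over the
background-normalized raw output, i.e. against the fitted background
sample; analyses that normalize over all landscape cells will print lnL
on a different scale, which affects absolute AIC values but not
within-analysis comparisons.

Bootstrap replicates draw 80% of the used points *with replacement*
(the bootstrap replicate type of the reference implementation); points
never drawn form the held-out set for test gain and AUC.

## The four-phase selection protocol

Phase 1 screens covariates by strength: percent contribution (objective
improvement credited, update by update, to the updated feature's parent
covariate — path-dependent by construction, which is why permutation
importance is reported beside it), permutation importance (10 seeded
permutations per covariate of its values across all rows, AUC drop
normalised to sum 100), and jackknife only/without gains with the
advancement rule "only-gain ≥ 2.5" (`exp(2.5) ≈ 12.2`-fold likelihood
improvement over null) made explicit and configurable. Phase 2–3
candidates come from `enumerate_uncorrelated_models()`: exactly one
covariate from each correlated group (pairwise Pearson R² or Cramér's V
strictly above 0.65; mixed pairs use decile binning of the continuous
member, a numeric stand-in for the original box-plot judgment) plus all
singletons. `bootstrap_aic_compare()` fits every candidate on identical
bootstrap resamples and ranks by median AIC; each replicate's AIC is
computed on the full used sample so candidates are compared on the same
data. Phase 4 is `rm_sweep()` over RM = 1.0–5.0 by 0.5.

The protocol, not its study-specific outcome, is the deliverable: on
synthetic designs where three named covariates generate the selection and
three correlated decoys shadow them, the Phase-3 ranking recovers the
generating trio (the acceptance checks run this over ten seeds).

## P/E classification

The continuous Boyce (P/E) curve uses overlapping bins of width 0.02
centred every 0.002 from 0.02 to the maximum prediction; per bin,
P = share of used predictions, E = share of available predictions. Bins
with E = 0 are undefined and excluded. Smoothing is a fixed-span
local-linear running smoother (span 0.2 of defined bins): the original
analysis used R's cross-validated supersmoother purely as a visual and
computational aid and found breakpoints insensitive to smoothing, so a
simpler smoother with one interpretable parameter is preferred; it
reproduces straight lines exactly, which the tests exploit.

The first break is forced at the largest bin centre with P/E < 1 —
habitat used below its availability is unsuitable by construction. Above
it, `fit_breakpoints()` fits a continuous piecewise-linear curve by OLS
for *every* combination of k interior breakpoints over the candidate bin
centres and keeps the SSE minimiser (ties to the lexicographically
smallest set, so the search is deterministic). Restricting candidates to
bin centres keeps the direct search exact and finite; because the full
grid can hold several hundred centres, a `max_candidates` guard (default
22) thins candidates to an evenly spaced subset before the still-
exhaustive search. Default k = 5 matches the best fit of the motivating
analysis; the pipeline default is k = 3, which yields the five-class
scheme (unsuitable/marginal/low/medium/high) directly without manual
merging. Post-hoc removal of anomalous or immaterial breakpoints is
supported only as an explicit, logged `merges` argument — expert judgment
is modelled as an input, never automated.

Class intervals are left-closed, right-open with a closed top (printed
class bounds reuse endpoints, so a convention had to be imposed); the
boundary value 0.19-style lower bound of "low" therefore counts as low,
which also fixes the inclusive ≥ threshold convention used in evaluation.

## Patch delineation

Cells of low-or-better habitat are polygonized with 4-connectivity
(diagonal contact does not join patches) into exterior rings — holes are
irrelevant here because the polygons only seed buffer groups. Buffering
by 80.25 m (the 5-acre radius: trees within it influenced the window
covariates inside the patch) is done analytically: two mask polygons'
buffers dissolve into one region exactly when the polygons are within
2 × 80.25 m, and a tall TAO (≥ 50 m) belongs to a dissolved region when
it is within 80.25 m of a member polygon. One concave hull is computed
per dissolved group (merged groups yield one hull — the natural reading
when buffers of nearby fragments overlap); groups with fewer than three
non-collinear TAOs are dropped with a warning, since one or two trees do
not delineate a stand. The hull is the edge-digging k-nearest-neighbour
construction with concavity 0.8 and length threshold 0; concavity → ∞
recovers the convex hull, which the tests verify against a standard
convex-hull routine.

Perimeter smoothing is the 60-m outward / 55-m inward buffer pair: a
morphological closing by 55 m (filling bays narrower than ~110 m)
composed with a residual 5-m dilation, so the result always contains the
input. The outward distance field is evaluated exactly from the polygon
edges; the inward step needs the distance transform of a region with no
closed form, so it runs on a working grid (default 1 m in the geometry
tests, 2 m in the pipeline) via a Euclidean distance transform, and the
smoothed polygon is traced from that grid. At working resolution h the
boundary is accurate to about one cell diagonal; containment of the input
is guaranteed for h below the 5-m net margin, and on convex inputs the
result's area matches the Steiner formula `A + 5P + 25π` to a few parts
per thousand at h = 1 m, which is the tested tolerance.

## Evaluation

AUC is the Mann–Whitney probability that a used score exceeds an
available score, ties counted half. The confusion matrix follows the
two-sample bookkeeping: negatives are the available points *not* labelled
used (so with 117,804 available and 1,080 used points the negatives are
116,724), even though the model's background retains the used points;
both conventions are supported and the subtraction one is the default
because the printed contingency arithmetic uses it. Sensitivity,
positive predictive value and kappa come from the standard 2×2 closed
forms, computed in exact double arithmetic with the kappa numerator and
denominator exposed for inspection. Marginal response curves vary one
covariate over its available range with all others held at available
means, with a mean ± SD band over bootstrap replicates.

## The synthetic forest generator

`forest_scenario()` emulates the landscape structure the analysis
assumes: a second-growth matrix (homogeneous Poisson stems, default
150/ha, lognormal heights with median 28 m and ~1% above 50 m) containing
old-growth patches with an extra Poisson layer of tall trees (support
clipped to [50, 120] m; the demonstration scenario uses 20 stems/ha
uniform on 60–105 m, within the "up to ~25/ha of 60-m-and-taller trees"
regime the analysis targets). Crowns are paraboloids of radius 0.1 ×
height — the simplest shape giving each tree one strict maximum — and a
cell of the rendered DSM takes the maximum over crowns, so adding a tree
never lowers the surface. An optional cluster mode adds stump-sprout
leaders within 1 m of a parent stem but is off by default. The default
synthetic DSM resolution is 1 m: fine enough to preserve local-maxima
behaviour, coarse enough for desk-scale grids (the 0.25-m resolution of
survey-grade surfaces is a parameter away). All randomness flows from one
scenario seed; generation is byte-reproducible.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: LiDAR returns, pulse density and
occlusion noise; terrain (ground is flat zero); crown asymmetry and
species mixtures; spatial inhibition or clustering beyond the optional
leader mode; gradual stand-age mosaics (used polygons coincide exactly
with generated patches, so real-world label noise at stand edges is
absent); and the climate/biogeographic covariate families, which enter
the real analysis only as pre-made rasters. Synthetic results
demonstrate correctness of the machinery and behaviour under the stated
statistical structure, not field performance.

## Problem sizes and numerical conventions

The shipped test and demonstration scales are chosen for single-CPU desk
use: a 120-ha demonstration landscape (1200 × 1000 m at 1-m DSM
resolution, 200 × 240 analysis grid), 3,000 BAS points (1 per 0.04 ha —
far denser than a landscape-scale survey design because a 120-ha scene
must still yield ~10² used points), 10 bootstrap replicates, ten-seed
recovery loops, and a 2-m smoothing grid in the pipeline. Convergence
tolerance 1e-5 (1e-9/1e-10 where tests compare against direct-search
optima); breakpoint ties broken lexicographically; plateau ties by
row-major centroid rule; half-open cell lookup `[x0, x0 + res)`;
rasters exchanged as ESRI ASCII grids, polygons as GeoJSON, models as
JSON — all plain text.

## Known limitations

- The coordinate-descent solver is pure R; landscapes beyond a few
  hundred thousand background points or a few thousand features will be
  slow.
- The exhaustive breakpoint search is exponential in k; the candidate
  guard trades grid resolution for exactness of the search over the
  thinned grid.
- Patch polygons carry exterior rings only; a patch with a genuine
  interior hole (a clearing wider than the smoothing closure) would be
  reported filled.
- Absolute AIC values depend on the background-normalization convention
  (see above); compare AIC only within one analysis.
- The concave hull guarantees containment of its input points and a
  simple (non-self-intersecting) ring, but like all concavity-parameter
  hulls its exact shape between points is a modelling choice, not an
  estimate.
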