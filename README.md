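# canopyhsm

Habitat suitability modelling from canopy height surfaces, for forest
ecologists and conservation planners who need to locate potential
old-forest nesting habitat — the motivating case is the marbled murrelet
(*Brachyramphus marmoratus*), a seabird that nests on the limbs of tall,
old conifers — from high-resolution canopy structure data.

The package implements the full analysis chain as reusable, tested R
functions:

1. **Tree approximate objects (TAOs).** Individual trees are extracted
   from a canopy digital surface model (DSM) as local maxima within a
   circular window: `extract_taos()`.
2. **Moving-window covariates.** On a 5-m analysis grid, circular-window
   statistics of tall trees (counts per acre, sum and standard deviation
   of heights, by height class and window area in acres):
   `tao_window_stat()`, with the final model's trio — density of TAOs
   ≥ 60 m, and the sum and SD of heights of TAOs ≥ 50 m, each in 5-acre
   windows — as the `final3_stack()` preset.
3. **Balanced acceptance sampling.** A random-start Halton-sequence (bases
   2, 3) spatially balanced sample labels points *used* when they fall in
   occupied-habitat polygons at least 20 m from the boundary; every point
   stays in the *available* pool: `bas_points()`, `label_samples()`.
4. **Maximum-entropy model.** The two-sample presence-background model
   with linear, quadratic, product and hinge features and L1 penalties
   scaled by a regularization multiplier (RM). The penalized objective

   ```
   Q(β) = mean_used β'f(x) − log Σ_available exp(β'f(x)) − Σ_j λ_j |β_j|
   ```

   is maximised by cyclic coordinate ascent with soft-thresholding;
   predictions come raw (background-normalized, `predict_raw()`) or as the
   scaled logistic habitat suitability index `HSI = r e^H / (1 + r e^H)`
   (`predict_logistic()`), with training gain, AIC (`2k − 2 lnL` with `k`
   the nonzero coefficients) and bootstrap replicates.
5. **Model selection.** The four-phase protocol: Pearson R² / Cramér's V
   correlation screening at 0.65, percent contribution, permutation
   importance and jackknife gains, enumeration of candidate models with no
   correlated pair, bootstrap-AIC ranking, and an RM sweep over 1.0–5.0 in
   steps of 0.5.
6. **P/E habitat classification.** The continuous predicted-to-expected
   (Boyce) ratio curve in overlapping HSI bins (width 0.02, step 0.002),
   a fixed-span local-linear smoother, the forced break at the largest HSI
   with P/E < 1, and an exhaustive least-squares search for piecewise-linear
   breakpoints that define the habitat classes
   (unsuitable/marginal/low/medium/high).
7. **Patch delineation.** Cells of low-or-better habitat are polygonized,
   buffered by the 5-acre window radius (80.25 m); tall TAOs (≥ 50 m) in
   each dissolved buffer are wrapped in a concave hull (concavity 0.8) and
   smoothed by a 60-m-out / 55-m-in morphological buffer pair.
8. **Evaluation.** AUC (Mann–Whitney), thresholded confusion matrix,
   sensitivity, positive predictive value, Cohen's kappa, and marginal
   response curves.

Because the LiDAR and survey data behind such analyses are typically
proprietary, the package ships a **synthetic forest generator**
(`forest_scenario()`, `generate_stem_map()`, `render_dsm()`): a
second-growth Poisson matrix with embedded old-growth patches of tall
trees whose paraboloid crowns render into a canopy surface. Every stage of
the pipeline is testable end-to-end on these landscapes.

## Worked example

```r
library(canopyhsm)
cfg <- pipeline_config(scenario = demo_scenario(seed = 11), seed = 11)
res <- run_pipeline(cfg, out_dir = "run1")
```

```
[simulate] scenario seed 11
[taos] window 2 m, min height 0 m
[taos] 14031 TAOs (193 >= 50 m)
[covariates] final trio on 200 x 240 @ 5 m grid
[sample] 3000 BAS points (1 per 0.04 ha), 20 m exclusion
[sample] 120 used / 3000 available
[fit] RM 2, classes linear+quadratic+product+hinge, 50 knots
[fit] 7/222 nonzero features, gain 2.946
[classify] forced break 0.052, interior {0.264, 0.312, 0.536}
[patches] buffer 80.25 m, concavity 0.8, smoothing 60/55 m
[patches] 1 patch(es)
[evaluate] AUC 0.979, sensitivity 0.967, PPV 0.823, kappa 0.884 @ 0.264
```

Reading the output: the 120-ha synthetic landscape holds one 6.6-ha
old-growth patch. Of 14,031 detected trees, 193 are 50 m or taller and
almost all sit in the patch, so the three moving-window covariates
separate the patch strongly; the fitted model keeps 7 features, and its
training gain of 2.95 nats means used locations are about `exp(2.95) ≈ 19`
times more likely under the model than under a uniform background. The
P/E curve crosses 1.0 at HSI 0.052 (the forced unsuitable break), the
breakpoint search places the low-class boundary at 0.264, and at that
threshold the model finds 96.7% of used points (sensitivity) with an AUC
of 0.979. Patch delineation recovers exactly one habitat patch whose
smoothed polygon contains every planted tall tree. All artifacts (DSM,
TAOs, covariate grids, sample, model, P/E curve, class raster, patch
polygons, metrics) land in `run1/` with MD5 hashes in `manifest.json`;
rerunning with the same seed reproduces every hash.

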