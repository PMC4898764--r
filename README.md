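# droughtgaps

Landscape analysis of drought-induced forest canopy gaps.

Severe droughts can kill forest canopy in discrete patches. For landscape
ecologists studying such dieback events from aerial surveys, `droughtgaps`
turns a table of delineated gap patches (centroid, area m², perimeter m)
into the standard disturbance-regime characterization and relates the patch
characteristics to environmental gradients:

* **Patch metrics** — size summaries in hectares; the shape index
  `s = P / (2·sqrt(pi·A))` (perimeter relative to an equal-area circle,
  size-invariant, ≥ 1);
* **Size distribution** — continuous power-law (Pareto) tail
  `P(X > x) = (x/xmin)^(1−α)` fitted by the closed-form maximum-likelihood
  estimator `α̂ = 1 + n / Σ ln(xᵢ/xmin)` above a fixed minimum mapping unit
  (default 0.3 ha), with the Kolmogorov–Smirnov D and a parametric
  bootstrap adequacy p-value (draw from the fitted law, refit, recompute D);
* **Clustering** — quartic (biweight) kernel density of patch centroids,
  `K_h(d) = 3/(π h²)·(1 − (d/h)²)²` for `d ≤ h`, on a raster grid
  (defaults: 2-km radius, 30-m cells, patches·km⁻²), attributed back to
  each patch at its centroid cell;
* **Environmental associations** — every monthly climate variable expanded
  into 20 temporal parameterizations (4 grains: Feb / Dec–Feb / Sep–Feb /
  water year × 5 extents: historic mean / current / % of historic /
  anomaly / current+historic), the minimum-AIC one selected per response;
  then forward stepwise Gaussian GLMs of the log-transformed patch
  characteristics with a ΔAIC > 2.0 entry rule, collinearity screening,
  and residual spatial diagnostics (coordinate correlations, Mantel
  permutation tests);
* **Synthetic landscapes** — a fully seeded generator (Thomas-process
  clustered patches with covariate-linked Pareto sizes, drought-anomaly
  climate cubes, smooth terrain/stand fields) so the entire pipeline is
  testable without any external rasters.

Data containers are S4 (`PatchSet`, `RasterGrid`/`StaticRaster`/
`DensitySurface`, `ClimateCube`, `PowerLawFit`, `GlmFit`) with validity
checks and accessors. I/O is plain text: CSV patch tables, GeoJSON
polygons/flightlines, ESRI ASCII grids.

## Worked example

A synthetic stand-in survey at the study scale (~226 patches over a 2-km
corridor, Pareto sizes, α = 2.69 above 0.3 ha), through the patch stage:

```r
library(droughtgaps)
cfg  <- syntheticConfig(seed = 42, alphaTrue = 2.69,
                        sizeEffects = numeric(0), densityEffects = numeric(0))
land <- generateLandscape(cfg, variables = character(0))
land$patches
#> PatchSet with 238 patches [unit: m]
#>   area (ha): 0.30-11.06 (mean 0.70)
#>   flightline: yes

run   <- runConfig(seed = 42, out_dir = "gap-results", n_boot = 1000)
stage <- runPatchStage(run, land$patches)
stage$fit
#> Continuous power law: alpha = 2.7269 (xmin = 0.3 ha, n = 238)
#>   loglik = 40.742, KS D = 0.0556
#>   bootstrap p = 0.220 (1000 replicates, seed 42)

round(c(mean = mean(patchAttr(stage$patches, "kernel_density")),
        min  = min(patchAttr(stage$patches, "kernel_density")),
        max  = max(patchAttr(stage$patches, "kernel_density"))), 2)
#> mean  min  max
#> 1.06 0.24 2.60
```

Reading: the fitted exponent (2.73) recovers the generating 2.69 within its
sampling error `(α−1)/√n ≈ 0.11`; KS D ≈ 0.06 with bootstrap p = 0.22 says
the Pareto tail is adequate; the minimum density attribute 0.24 is the
closed-form self-contribution of an isolated patch, `3/(π·2²)` patches·km⁻²
at a 2-km kernel, and patches in the densest hotspot reach 2.6. The stage
also writes `size_summary.csv`, `shape_summary.csv`, `power_law_fit.csv`,
`size_histogram.csv` (log–log histogram table), the density surface as an
ESRI ASCII grid, the attributed patch table, and a reproducibility
manifest into `gap-results/`.

With climate cubes and static rasters (real or from
`generateLandscape()`), `runAssociationStage()` adds, per response, the
20-row parameterization-selection table, the final model
(term/coefficient/SE/t/p with AIC and R² footer), the stepwise trace and
the spatial diagnostics. A thin CLI over the same functions is installed
at `inst/scripts/droughtgaps-cli.R` (subcommands `validate`, `generate`,
`patch-stats`, `associate`).

For real surveys, `readPatchTable()` ingests the S1-style CSV schema
(centroid x/y, area m², perimeter m; configurable column map, positional
fallback), `readPatchPolygons()` derives the same fields from GeoJSON
polygons by the shoelace formula, and both reject lon/lat-range
coordinates and records violating the isoperimetric bound
`P ≥ 2·sqrt(π·A)` (a unit-mismatch signal) with row-level reports.

## Methods

The methods vignette
(`vignettes/drought-gap-landscape-analysis.Rmd`) documents the models and
their assumptions, every tunable parameter with units and defaults, what
the synthetic generator does and does not emulate, the identifiability
limits of the extent selection, numerical edge cases, and known
limitations.
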