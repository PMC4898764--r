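Package: droughtgaps
Title: Landscape Analysis of Drought-Induced Forest Gap Patches
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the landscape configuration of discrete
    drought-impact canopy gaps and relating it to environmental gradients.
    Provides patch-level spatial metrics (size, shape index, kernel-density
    clustering), continuous power-law (Pareto) size-distribution fitting by
    maximum likelihood with Kolmogorov-Smirnov and bootstrap goodness-of-fit,
    quartic-kernel hotspot surfaces on regular raster grids, factorial
    temporal parameterization (grain x extent) of monthly climate series with
    AIC-based selection, forward stepwise Gaussian GLMs with a delta-AIC
    stopping rule, collinearity screening, Mantel tests for residual spatial
    autocorrelation, and a seeded synthetic-landscape generator (clustered
    Thomas-process patches with covariate-linked power-law sizes) so the full
    pipeline is testable without external rasters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'geometry.R'
    'raster-grid.R'
    'patch-io.R'
    'patch-metrics.R'
    'hotspot-density.R'
    'climate-features.R'
    'association-models.R'
    'synthetic-data.R'
    'pipeline.R'
    'droughtgaps-package.R'
RoxygenNote: 7.3.3
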