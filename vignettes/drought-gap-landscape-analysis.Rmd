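---
title: "Methods: landscape analysis of drought-induced forest gaps"
author: "droughtgaps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landscape analysis of drought-induced forest gaps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droughtgaps)
```

## The problem

Severe drought can kill forest canopy in discrete patches rather than
diffusely. Treating those patches as the unit of analysis turns a dieback
event into a landscape-ecology question: how large are the gaps, how
convoluted are their boundaries, how strongly do they cluster, and which
environmental gradients — meteorological water balance, terrain-driven
moisture, stand structure — predict where the damage concentrates?
`droughtgaps` implements that analysis as a reusable, testable pipeline for
aerial-survey patch data (centroid, area, perimeter per patch), with a
seeded synthetic-landscape generator standing in for the climate and
terrain rasters that real applications would supply.

## Patch-level metrics

**Size.** Areas are reported in hectares (m²/10,000) with mean, sample
(n−1) standard deviation and range. Because disturbance-gap size
distributions are strongly right-skewed, the distributional summary is the
exponent of a continuous power law (Pareto) fitted to all sizes at or above
the survey's minimum mapping unit:

$$P(X > x) = (x/x_{\min})^{1-\alpha}, \qquad x \ge x_{\min} = 0.3\ \mathrm{ha}.$$

The maximum-likelihood estimate is closed-form,
$\hat\alpha = 1 + n / \sum_i \ln(x_i/x_{\min})$. We fix $x_{\min}$ at the
0.3-ha mapping threshold rather than estimating it: the survey recorded
every patch above that size, so the observed distribution *is* the tail.
(`fitPowerLaw()` accepts any `xmin`, so the alternative — the smallest
observed size — is one argument away; the two coincide whenever the
smallest mapped patch sits at the threshold.) Goodness of fit uses the
Kolmogorov–Smirnov statistic evaluated at both step edges of the empirical
CDF, and — because the exponent is estimated from the same data — a
parametric bootstrap adequacy test: each replicate draws $n$ sizes from the
fitted law by inversion, refits the exponent, and recomputes D; the p-value
is the proportion of replicate D values at or above the observed one
(`bootstrapGof()`, default 1000 replicates, seed mandatory). The classical
one-sample KS p is reported alongside for reference only; with a fitted
parameter it is conservative. A Shapiro–Wilk screen documents that the
untransformed sizes are far from normal.

**Shape.** The shape index is the observed perimeter divided by the
perimeter of a circle of equal area, $s = P / (2\sqrt{\pi A})$: 1 for a
perfectly compact patch, larger for convoluted boundaries, and invariant
to patch size — unlike raw perimeter or perimeter/area. Patch records must
satisfy the isoperimetric bound $P \ge 2\sqrt{\pi A}$; the readers reject
violations beyond a 1e-9 relative tolerance rather than clamping them,
because a sub-circular perimeter almost always signals a unit mismatch
(e.g. km against m²).

**Clustering.** Patch density is estimated with a quartic (biweight)
kernel of finite radius $h$ = 2000 m on a 30-m raster grid:
$K_h(d) = \frac{3}{\pi h^2}(1 - (d/h)^2)^2$ for $d \le h$. Two printed
conventions pin this choice down: the kernel integrates to exactly one, so
grid mass equals patch count when the grid pads every centroid by $h$ (no
edge correction — the padding takes its place), and an isolated patch
contributes $3/(\pi \cdot 2^2) \approx 0.24$ patches·km⁻² at its own
centroid, the natural floor for the per-patch density attribute. Each patch
counts once regardless of area, densities are in patches·km⁻² and should be
read as a *relative* clustering measure, and each patch is attributed with
the value of the 30-m cell containing its centroid, without interpolation.

## Climate covariates: temporal grain × extent

Monthly gridded series (1975–2011; ~5-km cells) for precipitation, minimum
and maximum temperature, potential and actual evapotranspiration, their
ratio, and their difference are turned into patch-level covariates along
two axes. The *grain* selects which months of a labelled water year
(March–February; the drought year is 2010/11) are aggregated: February
only, December–February, September–February, or the full water year. Water
fluxes (precipitation, PET, AET, PET−AET) are summed over the grain's
months; state variables (temperatures, AET/PET) are averaged. The sum
versus mean split is the hydrological convention — the source analysis does
not state one — and it is recorded in the output metadata. For the AET/PET
composite we average the monthly ratio (its operation contract treats it as
a state variable); composing the ratio from grain-aggregated AET and PET
(ratio of sums) is a defensible alternative that would weight months by
their PET.

The *extent* expresses the drought year against the record: the historic
mean, the current (2010/11) value, current as a percentage of historic,
the current-minus-historic anomaly, or current and historic entered jointly
as two covariates. The historic mean is taken over every water-year label
the record covers *except* the drought year itself — the printed span names
the record, not the denominator, and excluding the drought year keeps the
anomaly a true departure from the pre-drought climate. PERCENT is computed
for temperature variables too (a warning notes that a percentage of a
quantity that crosses 0 °C needs care) and is flagged undefined wherever
the historic mean is zero.

All 4 × 5 = 20 combinations are enumerated in a fixed order (grains outer,
extents inner) and fitted as univariate — bivariate for the two-column
extent — Gaussian GLMs against each log-transformed patch characteristic;
the minimum-AIC parameterization per climate variable, re-selected per
response, carries forward. Ties break toward fewer columns, then
enumeration order.

## Association models

Responses (patch size, shape index, kernel density) are natural-log
transformed for homoscedasticity. Candidate predictors are the selected
climate features, the static covariates sampled at centroids (elevation,
topographic wetness index, tree cover, stand height), and the distance
from each centroid to the survey flightline — a nuisance covariate for
oblique-photography distortion. Variables enter by forward stepwise
selection: at each step the candidate with the largest AIC reduction
enters *only if* the reduction exceeds ΔAIC = 2.0, because a lone extra
parameter can shave AIC slightly without a real likelihood gain. There is
no removal phase; every candidate evaluation is recorded in a selection
trace. Two-column climate bundles enter and leave as one block. AIC uses
the full Gaussian log-likelihood (`stats::AIC`; k counts intercept, slopes
and error variance) — the convention cancels in comparisons but is fixed
and stated. R² is 1 − RSS/TSS.

Final models are screened for collinearity (all pairwise Pearson r;
|r| ≥ 0.7 flags a warning — removal is left to the analyst, warn-only by
default) and for residual spatial structure: Pearson correlations of
residuals against centroid x and y, and a Mantel test between the
Euclidean geographic distance matrix and the absolute-difference
dissimilarity of residuals. The Mantel p is one-sided over row/column
permutations; when $n! \le$ `nPerm` every permutation is enumerated and
the p is exact, otherwise `nPerm` (default 999) seeded random permutations
give $p = (1 + \#\{r^* \ge r\})/(n_{perm}+1)$.

## What the synthetic generator emulates — and what it does not

`generateLandscape()` produces the statistical structure the analysis
assumes, not any real landscape:

* **Survey geometry.** A 200 km × 4 km corridor (2 km either side of a
  straight flightline), mirroring a long aerial transect; ~226 expected
  patches, the surveyed sample size.
* **Clustering.** A Thomas process — Poisson parents (default 75 expected),
  Poisson offspring (mean ≈ 3), Gaussian displacement (sd 300 m) — with
  parent intensity log-linear in configured covariates. These defaults put
  the per-patch density attribute near 1 patch·km⁻² with isolated patches
  at the quartic floor, the regime the study describes.
* **Sizes.** Pareto(α = 2.7, x_min = 0.3 ha) multiplied by
  exp(Σ effects × covariates). The effect term is shifted so the
  multiplier is ≥ 1 everywhere: every area stays above the mapping
  threshold *and* the log-linear size model remains exactly correctly
  specified, so coefficient-recovery tests have a well-defined truth. The
  cost is that the marginal size distribution is a mixture of Paretos with
  shifted lower bounds whenever effects are nonzero; runs meant to emulate
  the published marginal (fixed-xmin fit, KS adequacy) therefore use zero
  size effects, and recovery runs accept a slightly distorted marginal.
* **Shapes.** Shape index 1 + lognormal(μ = −1.956, σ = 0.8326), i.e.
  mean excess 0.2 and sd 0.2, matching the published shape summary;
  perimeters follow as $s \cdot 2\sqrt{\pi A}$, so the isoperimetric bound
  holds by construction.
* **Climate.** Monthly fields = smooth spatial base gradient + seasonal
  climatology (Mediterranean regime: wet winters, hot dry summers) + white
  noise, with a drought anomaly added to the 2010/11 water year only: a
  45% precipitation deficit over the whole water year, heat excesses
  (+1.8 °C maximum, +1.2 °C minimum temperature) concentrated in
  spring/summer months, analogous deficits for the evapotranspiration
  variables. The anomaly's spatial pattern mixes a drought-wide component
  with seasonal-block components so that different temporal grains see
  genuinely different spatial patterns, as synoptic anomalies do — without
  this, grains differ only in noise and grain selection is not
  identifiable.
* **Terrain and stands.** Cosine-mixture random fields with
  field-appropriate wavelengths (TWI at hillslope scale 0.8–3 km,
  elevation 4–15 km, …). Short TWI wavelengths matter statistically: they
  decorrelate terrain from the long-wavelength climate anomaly, limiting
  spurious confounding between candidate covariates.

Not emulated: hydrological consistency between the climate variables,
DEM-derived TWI, recovery or repeat-disturbance dynamics, irregular
flightline geometry, photo-delineation error. Tests passing on this
generator therefore demonstrate the *estimators* behave as designed under
the assumed structure, not that any particular real landscape satisfies
that structure.

## Identifiability of the parameterization selection

One structural fact discovered while validating the selection procedure is
worth stating plainly: the two-column extent (current + historic) linearly
spans every single-column extent — the anomaly is the difference of its
columns, current and historic *are* its columns. Min-AIC therefore prefers
the two-column model over the true single-column one whenever the
likelihood-ratio improvement exceeds 2, an asymptotic
$P(\chi^2_1 > 2) \approx 15.7\%$ event even when the single-column model is
exactly true. Exact recovery of a generating grain × extent pair is
consequently capped near 84% *at best*, and the percentage and anomaly
extents of additive variables are near-collinear (they differ only through
the spatial variation of the historic mean level), which costs much more at
realistic signal-to-noise. The replicate suites measure and report the
exact-pair rate, the grain-only rate, and the stepwise inclusion rate of
the underlying climate *variable*; users should read selected extents as
representatives of near-equivalent classes, not as sharp identifications.

## Numerical choices and degenerate inputs

* Polygon geometry (shoelace area, ring perimeter, area-weighted centroid)
  is computed relative to the ring's first vertex; at ~10⁶-m projected
  coordinates the raw cross products would lose ~6 digits to cancellation.
  Self-intersecting rings are rejected, as are lon/lat-range coordinates
  (the reader refuses to guess a projection).
* Grid lookups assign points on the extreme north/east edge to the last
  cell so a closed extent is fully covered; attribution is by containing
  cell, never interpolated.
* The density grid pads the centroid bounding box by one bandwidth and
  snaps the origin to whole cells, making attributes exactly
  translation-equivariant for whole-cell shifts.
* Constant (zero-variance) inputs error early: Shapiro–Wilk on identical
  sizes, GLMs on aliased columns (the offending columns are named),
  correlations on zero-variance columns (flagged, excluded).
* Bootstrap (≥ 100 replicates) and Mantel (≥ 99 permutations) refuse
  smaller runs; both require an explicit seed.

## Problem sizes in the test and acceptance suites

The packaged suites choose sizes that exercise every claim at meaningful
power: stand-in patch stages at the survey scale (~226 patches, ~2 million
density cells); effect-recovery at 80 replicates in the test suite and 200
in `scripts/acceptance.R`; null calibration of the bootstrap and Mantel
p-values at 200 replicates each; exponent consistency at n = 10,000. The
null false-entry rate of the ΔAIC rule is regression-tested against a
frozen baseline of 0.045 per candidate, estimated once from 200 null
landscapes (the asymptotic theory value is $P(\chi^2_1 > 4) = 0.0455$).

## Known limitations

* The association models are ordinary least squares on log responses;
  spatial-error or mixed models are out of scope, and the Mantel check
  only *detects* residual structure, it does not correct for it.
* Only the power law is fitted to sizes; no likelihood-ratio comparison
  against lognormal or exponential alternatives.
* Kernel density has no edge correction beyond padding and no adaptive
  bandwidth; hotspot significance testing is out of scope.
* The generator's covariate effects on patch size are multiplicative with
  a min-shift; real effect structure could censor at the mapping threshold
  instead, which would attenuate recovered coefficients.
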