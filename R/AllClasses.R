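#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Regular raster grid
#'
#' Lightweight container for a single-band regular grid in a projected,
#' metre-based coordinate system. Values are stored as a matrix whose first
#' row is the *northern-most* row, matching ESRI ASCII grid order, with
#' `xll`/`yll` the coordinates of the lower-left corner of the extent.
#'
#' @slot xll,yll x/y coordinate (m) of the lower-left corner.
#' @slot cellSize cell edge length (m).
#' @slot values numeric matrix of cell values (row 1 = top row).
#' @exportClass RasterGrid
setClass("RasterGrid",
  representation(xll = "numeric", yll = "numeric",
                 cellSize = "numeric", values = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
        object@cellSize <= 0)
      msg <- c(msg, "cellSize must be a single positive number")
    if (length(object@xll) != 1L || length(object@yll) != 1L ||
        !is.finite(object@xll) || !is.finite(object@yll))
      msg <- c(msg, "xll and yll must be single finite numbers")
    if (!is.numeric(object@values))
      msg <- c(msg, "values must be a numeric matrix")
    if (length(msg)) msg else TRUE
  })

#' Named static environmental raster
#'
#' A [RasterGrid-class] carrying the name of the environmental covariate it
#' represents (e.g. `"elevation"`, `"twi"`, `"tree_cover"`, `"stand_height"`).
#'
#' @slot name covariate name.
#' @exportClass StaticRaster
setClass("StaticRaster", contains = "RasterGrid",
  representation(name = "character"),
  validity = function(object) {
    if (length(object@name) != 1L || !nzchar(object@name))
      "name must be a single non-empty string" else TRUE
  })

#' Kernel density surface
#'
#' A [RasterGrid-class] of patch-centroid kernel densities in patches per
#' square kilometre, with the estimation bandwidth and kernel recorded.
#'
#' @slot bandwidth kernel radius (m).
#' @slot kernel kernel name; only `"quartic"` is implemented.
#' @exportClass DensitySurface
setClass("DensitySurface", contains = "RasterGrid",
  representation(bandwidth = "numeric", kernel = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@bandwidth) != 1L || object@bandwidth <= 0)
      msg <- c(msg, "bandwidth must be a single positive number")
    if (!identical(object@kernel, "quartic"))
      msg <- c(msg, "kernel must be 'quartic'")
    if (any(object@values < 0, na.rm = TRUE))
      msg <- c(msg, "density values must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' Collection of drought-impact patches
#'
#' Ordered collection of delineated canopy-gap patches. The `patches` slot is
#' a data frame with mandatory columns `id`, `x`, `y` (centroid, m), `area`
#' (m^2) and `perimeter` (m); any further numeric columns are per-patch
#' attributes (patch metrics, environmental covariates sampled at the
#' centroid). Optional polygon rings (one closed ring matrix per patch, m)
#' and a flightline polyline support geometry-derived fields and the
#' distance-to-flightline covariate.
#'
#' Validity enforces unique ids, positive area and perimeter, and the
#' isoperimetric bound `perimeter >= 2*sqrt(pi*area)` (no simple polygon can
#' beat the circle), within a relative tolerance of 1e-9.
#'
#' @slot patches data frame of patch records.
#' @slot polygons named list of ring coordinate matrices (may be empty).
#' @slot flightline two-column coordinate matrix of the survey flightline,
#'   or NULL.
#' @slot unit declared linear unit; must be "m".
#' @exportClass PatchSet
setClass("PatchSet",
  representation(patches = "data.frame", polygons = "list",
                 flightline = "matrixOrNULL", unit = "character"),
  prototype(polygons = list(), flightline = NULL, unit = "m"),
  validity = function(object) {
    p <- object@patches
    msg <- character()
    need <- c("id", "x", "y", "area", "perimeter")
    if (!all(need %in% names(p)))
      return(paste("patches must have columns:", paste(need, collapse = ", ")))
    if (!identical(object@unit, "m"))
      msg <- c(msg, "unit must be 'm' (projected metre coordinates)")
    if (anyDuplicated(p$id))
      msg <- c(msg, "patch ids must be unique")
    if (nrow(p)) {
      if (any(p$area <= 0) || any(p$perimeter <= 0))
        msg <- c(msg, "area and perimeter must be positive")
      else {
        pmin_iso <- 2 * sqrt(pi * p$area)
        bad <- p$perimeter < pmin_iso * (1 - 1e-9)
        if (any(bad))
          msg <- c(msg, paste0("isoperimetric bound violated for id(s): ",
                               paste(p$id[bad], collapse = ", ")))
      }
    }
    if (length(object@polygons) &&
        !all(names(object@polygons) %in% p$id))
      msg <- c(msg, "polygon names must match patch ids")
    if (length(msg)) msg else TRUE
  })

#' Fitted continuous power-law (Pareto) size distribution
#'
#' Maximum-likelihood fit of the tail model
#' \eqn{P(X > x) = (x/x_{min})^{1-\alpha}} for \eqn{x \ge x_{min}}, with
#' Kolmogorov-Smirnov goodness of fit and (once computed) the parametric
#' bootstrap adequacy p-value. Slots left `NA` until the bootstrap runs.
#'
#' @slot xmin lower truncation of the fitted tail (ha).
#' @slot alpha fitted exponent (> 1).
#' @slot n number of sizes at or above xmin.
#' @slot loglik maximized log-likelihood.
#' @slot ksD Kolmogorov-Smirnov D statistic.
#' @slot pValue bootstrap goodness-of-fit p-value (NA until computed).
#' @slot nBoot bootstrap replicates used (NA until computed).
#' @slot seed RNG seed of the bootstrap (NA until computed).
#' @exportClass PowerLawFit
setClass("PowerLawFit",
  representation(xmin = "numeric", alpha = "numeric", n = "integer",
                 loglik = "numeric", ksD = "numeric", pValue = "numeric",
                 nBoot = "numeric", seed = "numeric"),
  prototype(pValue = NA_real_, nBoot = NA_real_, seed = NA_real_,
            ksD = NA_real_),
  validity = function(object) {
    msg <- character()
    if (object@xmin <= 0) msg <- c(msg, "xmin must be positive")
    if (object@alpha <= 1) msg <- c(msg, "alpha must exceed 1")
    if (!is.na(object@ksD) && (object@ksD < 0 || object@ksD > 1))
      msg <- c(msg, "ksD must lie in [0, 1]")
    if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
      msg <- c(msg, "pValue must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Monthly gridded climate series
#'
#' One meteorological/hydrological variable on a coarse regular grid with
#' complete monthly coverage over a span of calendar years (January of
#' `startYear` through December of the last year). The `values` slot is a
#' 3-D array `[row, col, month]` in the same row order as
#' [RasterGrid-class]; `metadata` may carry generator provenance such as the
#' imposed drought-anomaly field.
#'
#' @slot variable one of `"precipitation"`, `"t_min"`, `"t_max"`, `"pet"`,
#'   `"aet"`, `"aet_pet"`, `"pet_minus_aet"`.
#' @slot xll,yll,cellSize grid geometry (m).
#' @slot startYear first calendar year of the monthly series.
#' @slot values array `[nrow, ncol, 12*nYears]`.
#' @slot metadata free-form list.
#' @exportClass ClimateCube
setClass("ClimateCube",
  representation(variable = "character", xll = "numeric", yll = "numeric",
                 cellSize = "numeric", startYear = "integer",
                 values = "array", metadata = "list"),
  prototype(metadata = list()),
  validity = function(object) {
    msg <- character()
    if (!object@variable %in% climateVariables())
      msg <- c(msg, paste("unknown variable:", object@variable))
    d <- dim(object@values)
    if (length(d) != 3L || d[3L] %% 12L != 0L)
      msg <- c(msg, "values must be [row, col, month] with whole years")
    if (object@variable %in% c("precipitation", "pet", "aet") &&
        any(object@values < 0, na.rm = TRUE))
      msg <- c(msg, "flux variables must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' Gaussian GLM fit with AIC
#'
#' Ordinary Gaussian identity-link fit of a log-transformed patch
#' characteristic on environmental predictors, with the coefficient table,
#' AIC (full Gaussian log-likelihood convention, `stats::AIC`), variance
#' explained and per-patch residuals.
#'
#' @slot response response name.
#' @slot terms data frame with columns term, coefficient, SE, t, p.
#' @slot aic Akaike information criterion.
#' @slot rSquared 1 - RSS/TSS.
#' @slot residuals per-observation residuals in input order.
#' @slot n number of observations.
#' @exportClass GlmFit
setClass("GlmFit",
  representation(response = "character", terms = "data.frame",
                 aic = "numeric", rSquared = "numeric",
                 residuals = "numeric", n = "integer"),
  validity = function(object) {
    msg <- character()
    if (!all(c("term", "coefficient", "SE", "t", "p") %in%
             names(object@terms)))
      msg <- c(msg, "terms must have columns term, coefficient, SE, t, p")
    if (nrow(object@terms) < 1L)
      msg <- c(msg, "model must contain at least an intercept")
    if (object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12)
      msg <- c(msg, "rSquared must lie in [0, 1]")
    if (length(object@residuals) &&
        abs(mean(object@residuals)) > 1e-8 * max(1, stats::sd(object@residuals)))
      msg <- c(msg, "residuals must average to ~0 (intercept present)")
    if (length(msg)) msg else TRUE
  })

#' Supported climate variable names
#'
#' Flux variables (`precipitation`, `pet`, `aet`, `pet_minus_aet`) are summed
#' over a temporal grain; state variables (`t_min`, `t_max`, `aet_pet`) are
#' averaged.
#' @return character vector of variable names.
#' @export
climateVariables <- function() {
  c("precipitation", "t_min", "t_max", "pet", "aet", "aet_pet",
    "pet_minus_aet")
}

#' @rdname climateVariables
#' @param variable variable name.
#' @return `isFluxVariable` returns TRUE if the variable is accumulated
#'   (summed) over months rather than averaged.
#' @export
isFluxVariable <- function(variable) {
  variable <- match.arg(variable, climateVariables())
  variable %in% c("precipitation", "pet", "aet", "pet_minus_aet")
}
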