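#' Configuration for the synthetic landscape generator
#'
#' Bundles every knob of the generator with defaults mirroring the study
#' conditions: ~226 expected patches along a surveyed corridor 2 km either
#' side of the flightline, Pareto sizes with exponent 2.7 above the 0.3-ha
#' minimum mapping unit, shape indices `1 + lognormal` with mean excess 0.2
#' and sd 0.2, a monthly climate record over 1975-2011 with a drought
#' anomaly in the 2010/11 water year (rainfall deficit, temperature excess,
#' seasonally weighted), smooth static covariate fields (elevation, TWI,
#' tree cover, stand height) and log-linear covariate effects on patch size
#' and on patch (parent) density.
#'
#' Climate effects are keyed by variable name; `generatingParams` records
#' which temporal parameterization of each variable drives the effect (the
#' quantity the AIC selection procedure is expected to recover).
#'
#' @param seed integer master seed; all draws derive from it.
#' @param domainWidth,domainHeight landscape extent (m).
#' @param origin lower-left corner in projected coordinates (m).
#' @param nParents expected Thomas-process parent count.
#' @param clusterSd Gaussian offspring displacement sd (m).
#' @param meanOffspring expected offspring per parent.
#' @param alphaTrue Pareto size exponent.
#' @param xmin minimum mapping unit (ha).
#' @param sizeEffects named numeric: log-linear slopes of patch size on
#'   covariates (static raster names or climate variable names).
#' @param densityEffects named numeric: log-linear slopes of parent
#'   intensity on covariates.
#' @param generatingParams named list mapping climate variable to
#'   `c(grain, extent)`.
#' @param shapeLognormal `c(mu, sigma)` of `log(shape - 1)`.
#' @param fieldAmplitude scales the static fields' spatial variation
#'   (0 gives constant fields).
#' @param climateNoiseSd named per-variable monthly white-noise sd.
#' @param droughtAnomaly named per-variable anomaly magnitude: a fraction
#'   (multiplicative) for water fluxes, an additive offset for temperatures
#'   and the AET/PET ratio.
#' @param anomalyMonths named list: months of the 2010/11 water year (1-12
#'   = Mar-Feb) carrying the anomaly.
#' @param staticCellSize,climateCellSize raster resolutions (m).
#' @return a list of class `syntheticConfig`.
#' @export
syntheticConfig <- function(
    seed = 1L,
    domainWidth = 200000, domainHeight = 4000,
    origin = c(400000, 6400000),
    nParents = 75, clusterSd = 300, meanOffspring = 226 / 75,
    alphaTrue = 2.7, xmin = 0.3,
    sizeEffects = c(twi = -0.12, t_max = -0.5),
    densityEffects = c(stand_height = -0.1),
    generatingParams = list(
      t_max = c(grain = "SONDJF", extent = "ANOMALY"),
      t_min = c(grain = "DJF", extent = "ANOMALY"),
      precipitation = c(grain = "WATER_YEAR", extent = "PERCENT"),
      aet = c(grain = "FEB", extent = "CURRENT")),
    shapeLognormal = c(mu = -1.956, sigma = 0.8326),
    fieldAmplitude = 1,
    climateNoiseSd = c(precipitation = 8, t_min = 0.8, t_max = 0.8,
                       pet = 6, aet = 5, aet_pet = 0.04,
                       pet_minus_aet = 6),
    droughtAnomaly = c(precipitation = -0.45, t_min = 1.2, t_max = 1.8,
                       pet = 15, aet = -0.30, aet_pet = -0.12,
                       pet_minus_aet = 20),
    anomalyMonths = list(precipitation = 1:12, t_min = 10:12,
                         t_max = 7:12, pet = 7:12, aet = 10:12,
                         aet_pet = 10:12, pet_minus_aet = 7:12),
    staticCellSize = 90, climateCellSize = 5000) {
  cfg <- as.list(environment())
  stopifnot(cfg$alphaTrue > 1, cfg$clusterSd > 0, cfg$xmin > 0,
            cfg$nParents >= 1, cfg$meanOffspring >= 1)
  class(cfg) <- "syntheticConfig"
  cfg
}

## Smooth random field: mixture of low-frequency cosine waves with seeded
## random wavelengths, directions and phases, standardized to sd 1.
cosineField <- function(nr, nc, cellSize, nWaves = 6,
                        wavelengths = c(4000, 16000)) {
  xc <- (seq_len(nc) - 0.5) * cellSize
  yc <- (seq_len(nr) - 0.5) * cellSize
  z <- matrix(0, nr, nc)
  for (k in seq_len(nWaves)) {
    lam <- stats::runif(1, wavelengths[1L], wavelengths[2L])
    th <- stats::runif(1, 0, pi)
    ph <- stats::runif(1, 0, 2 * pi)
    amp <- stats::runif(1, 0.5, 1)
    wave <- outer(yc * sin(th), xc * cos(th), `+`)
    z <- z + amp * cos(2 * pi * wave / lam + ph)
  }
  s <- stats::sd(z)
  if (s > 0) z <- z / s
  z
}

#' Generate the static covariate fields
#'
#' Smooth spatially autocorrelated fields over the domain: elevation (m),
#' topographic wetness index (unitless, right-skewed), percent tree cover
#' (clipped to [0, 100]) and stand height (m, positive). Deterministic
#' under the config seed; a zero `fieldAmplitude` yields constant fields.
#'
#' @param config a [syntheticConfig()].
#' @return named list of [StaticRaster-class] objects.
#' @export
generateStaticFields <- function(config) {
  set.seed(as.integer(config$seed) + 1L)
  cs <- config$staticCellSize
  nr <- ceiling(config$domainHeight / cs)
  nc <- ceiling(config$domainWidth / cs)
  a <- config$fieldAmplitude
  ## characteristic scales: terrain-driven fields (TWI) vary at hillslope
  ## scale, elevation and stand structure more broadly
  waves <- list(elevation = c(4000, 15000), twi = c(800, 3000),
                tree_cover = c(1000, 5000), stand_height = c(2000, 8000))
  z <- lapply(waves, function(wl) cosineField(nr, nc, cs, nWaves = 8,
                                              wavelengths = wl))
  mk <- function(v, name) new("StaticRaster", xll = config$origin[1L],
                              yll = config$origin[2L], cellSize = cs,
                              values = v[nr:1, , drop = FALSE], name = name)
  elev <- 250 + 60 * a * z[[1L]]
  twi <- 4 + 2 * exp(0.6 * a * z[[2L]])            # right-skewed
  cover <- pmax(pmin(55 + 18 * a * z[[3L]], 100), 0)   # matrix-first: keep dims
  height <- pmax(22 + 5 * a * z[[4L]], 1)
  list(elevation = mk(elev, "elevation"), twi = mk(twi, "twi"),
       tree_cover = mk(cover, "tree_cover"),
       stand_height = mk(height, "stand_height"))
}

climatology <- function(variable) {
  switch(variable,  # calendar months Jan..Dec, southern hemisphere
    precipitation = c(10, 15, 20, 45, 120, 180, 180, 140, 90, 55, 30, 15),
    t_max = 24 + 7.5 * cos(2 * pi * ((1:12) - 1.5) / 12),
    t_min = 10 + 5.5 * cos(2 * pi * ((1:12) - 2) / 12),
    pet = 140 + 80 * cos(2 * pi * ((1:12) - 1) / 12),
    aet = c(40, 35, 45, 55, 70, 75, 70, 65, 60, 55, 50, 45),
    aet_pet = pmin(0.95, pmax(0.05,
      0.45 + 0.3 * cos(2 * pi * ((1:12) - 7) / 12))),
    pet_minus_aet = pmax(0, 140 + 80 * cos(2 * pi * ((1:12) - 1) / 12) -
      c(40, 35, 45, 55, 70, 75, 70, 65, 60, 55, 50, 45)))
}

spatialAmplitude <- function(variable) {
  # multiplicative for fluxes (fraction), additive for states
  switch(variable, precipitation = 0.15, t_max = 1.5, t_min = 1.5,
         pet = 0.10, aet = 0.12, aet_pet = 0.06, pet_minus_aet = 0.15)
}

#' Generate a monthly climate cube with a drought-year anomaly
#'
#' Monthly fields 1975-2011 composed of a smooth spatial base gradient, a
#' seasonal climatology and white noise. The 2010/11 water year (March 2010
#' through February 2011) additionally receives a spatially varying anomaly
#' of the configured magnitude, applied only in the configured water-year
#' months (the drought's rainfall deficit spans the year; its heat excess
#' is concentrated in spring/summer). The anomaly's spatial pattern is a
#' mixture of a drought-wide component and a seasonal-block component, so
#' different temporal grains see genuinely different spatial patterns, as
#' real synoptic anomalies do. Flux-variable anomalies are multiplicative
#' fractions (e.g. -0.45 = 45% deficit at anomaly centres), temperature and
#' ratio anomalies additive. The imposed per-month anomaly fields
#' (magnitude x weight in [0, 1]) are stored in `metadata$anomalyMonthly`
#' (water-year month order), their mean over the anomaly months in
#' `metadata$anomaly`.
#'
#' @param config a [syntheticConfig()].
#' @param variable climate variable name.
#' @return a [ClimateCube-class] spanning 1975-2011.
#' @export
generateClimateCube <- function(config, variable) {
  variable <- match.arg(variable, climateVariables())
  vi <- match(variable, climateVariables())
  set.seed(as.integer(config$seed) + 10L + vi)
  cs <- config$climateCellSize
  nc <- ceiling(config$domainWidth / cs) + 2L       # one pad cell each side
  nr <- ceiling(config$domainHeight / cs) + 2L
  xll <- config$origin[1L] - cs
  yll <- config$origin[2L] - cs
  years <- 1975:2011
  nm <- 12L * length(years)
  clim <- climatology(variable)
  base <- cosineField(nr, nc, cs, wavelengths = c(10000, 30000))
  norm01 <- function(z) (z - min(z)) / max(1e-12, diff(range(z)))
  w0 <- norm01(cosineField(nr, nc, cs, wavelengths = c(8000, 25000)))
  vBlock <- replicate(4, norm01(cosineField(nr, nc, cs,
                                            wavelengths = c(8000, 25000))),
                      simplify = FALSE)          # MAM / JJA / SON / DJF
  amp <- spatialAmplitude(variable)
  noiseSd <- unname(config$climateNoiseSd[variable])
  mag <- unname(config$droughtAnomaly[variable])
  aMonths <- config$anomalyMonths[[variable]]       # 1-12 = Mar..Feb
  multiplicative <- variable %in% c("precipitation", "pet", "aet",
                                    "pet_minus_aet")
  vals <- array(0, dim = c(nr, nc, nm))
  anomalyMonthly <- lapply(1:12, function(wyM) {
    if (!wyM %in% aMonths) return(matrix(0, nr, nc))
    mag * (0.5 * w0 + 0.5 * vBlock[[(wyM - 1L) %/% 3L + 1L]])
  })
  for (y in seq_along(years)) {
    for (m in 1:12) {
      idx <- (y - 1L) * 12L + m
      lay <- if (multiplicative) clim[m] * (1 + amp * base)
        else clim[m] + amp * base
      # water-year month index of this calendar month within 2010/11
      wyM <- if (years[y] == 2010L && m >= 3L) m - 2L
        else if (years[y] == 2011L && m <= 2L) m + 10L else NA_integer_
      if (!is.na(wyM) && wyM %in% aMonths) {
        lay <- if (multiplicative) lay * (1 + anomalyMonthly[[wyM]])
          else lay + anomalyMonthly[[wyM]]
      }
      if (noiseSd > 0)
        lay <- lay + matrix(stats::rnorm(nr * nc, 0, noiseSd), nr, nc)
      if (variable %in% c("precipitation", "pet", "aet", "pet_minus_aet"))
        lay <- pmax(lay, 0)
      if (variable == "aet_pet") lay <- pmin(pmax(lay, 0.02), 0.98)
      vals[, , idx] <- lay
    }
  }
  meanAnom <- Reduce(`+`, anomalyMonthly[aMonths]) / length(aMonths)
  climateCube(variable, vals, xll = xll, yll = yll, cellSize = cs,
              startYear = 1975L,
              metadata = list(anomaly = meanAnom,
                              anomalyMonthly = anomalyMonthly,
                              anomalyMonths = aMonths,
                              multiplicative = multiplicative,
                              noiseSd = noiseSd))
}

covariateRaster <- function(name, fields, cubes, config) {
  if (name %in% names(fields)) return(fields[[name]])
  if (name %in% names(cubes)) {
    par <- config$generatingParams[[name]]
    if (is.null(par))
      stop("no generating parameterization configured for ", name)
    fr <- suppressWarnings(featureRasters(cubes[[name]], par[["grain"]],
                                          par[["extent"]], 2011L))
    return(fr[[1L]])     # COVARIATE bundles use the current column
  }
  stop("unknown effect covariate: ", name)
}

#' Generate a clustered patch set with covariate-linked sizes
#'
#' Centroids follow a Thomas cluster process: Poisson parents placed with
#' intensity log-linear in the configured density-effect covariates,
#' Poisson offspring counts, and Gaussian offspring displacement. Patch
#' areas are Pareto(`alphaTrue`, `xmin`) multiplied by
#' `exp(sum(sizeEffects * covariates))`; the effect term is shifted so the
#' multiplier is >= 1 everywhere, which keeps every area above the minimum
#' mapping unit (the log-linear model for size stays exactly correctly
#' specified) with a redraw guard as backstop. Perimeters come from a
#' sampled shape index `s = 1 + lognormal(mu, sigma)` via
#' `perimeter = s * 2 * sqrt(pi * area)`, so the isoperimetric bound holds
#' by construction.
#'
#' @param config a [syntheticConfig()].
#' @param fields output of [generateStaticFields()].
#' @param cubes named list of [ClimateCube-class] objects covering every
#'   climate variable named in the effect maps.
#' @return a [PatchSet-class] with the flightline attached.
#' @export
generatePatches <- function(config, fields, cubes = list()) {
  set.seed(as.integer(config$seed) + 100L)
  W <- config$domainWidth; H <- config$domainHeight
  ox <- config$origin[1L]; oy <- config$origin[2L]

  ## parent intensity over the static-field grid
  ref <- fields[[1L]]
  nr <- nrow(gridValues(ref)); nc <- ncol(gridValues(ref))
  logw <- matrix(0, nr, nc)
  for (nm in names(config$densityEffects)) {
    cov <- covariateRaster(nm, fields, cubes, config)
    xc <- ref@xll + (seq_len(nc) - 0.5) * ref@cellSize
    yc <- ref@yll + (nr - seq_len(nr) + 0.5) * ref@cellSize  # row 1 = north
    v <- matrix(valueAtPoints(cov, rep(xc, each = nr), rep(yc, times = nc),
                              outside = "na"), nr, nc)
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    logw <- logw + config$densityEffects[[nm]] * v
  }
  w <- exp(logw - max(logw))
  nPar <- stats::rpois(1L, config$nParents)
  if (nPar == 0L) nPar <- 1L                    # keep the landscape non-empty
  cellIdx <- sample.int(nr * nc, nPar, replace = TRUE, prob = as.vector(w))
  pr <- (cellIdx - 1L) %% nr + 1L
  pc <- (cellIdx - 1L) %/% nr + 1L
  px <- ref@xll + (pc - 1L + stats::runif(nPar)) * ref@cellSize
  py <- ref@yll + (nr - pr + stats::runif(nPar)) * ref@cellSize

  nOff <- stats::rpois(nPar, config$meanOffspring)
  if (sum(nOff) == 0L)
    stop("zero patches generated; increase nParents or meanOffspring",
         call. = FALSE)
  cx <- numeric(0); cy <- numeric(0)
  for (i in seq_len(nPar)) {
    if (nOff[i] == 0L) next
    for (j in seq_len(nOff[i])) {
      for (try in 1:100) {
        x <- px[i] + stats::rnorm(1, 0, config$clusterSd)
        y <- py[i] + stats::rnorm(1, 0, config$clusterSd)
        if (x >= ox && x <= ox + W && y >= oy && y <= oy + H) break
      }
      cx <- c(cx, min(max(x, ox), ox + W))
      cy <- c(cy, min(max(y, oy), oy + H))
    }
  }
  n <- length(cx)

  ## size effects at centroids, shifted so the multiplier never drops below 1
  eff <- numeric(n)
  for (nm in names(config$sizeEffects)) {
    cov <- covariateRaster(nm, fields, cubes, config)
    eff <- eff + config$sizeEffects[[nm]] *
      valueAtPoints(cov, cx, cy, outside = "error")
  }
  if (length(config$sizeEffects)) eff <- eff - min(eff)
  areaHa <- rPareto(n, config$xmin, config$alphaTrue) * exp(eff)
  for (r in 1:50) {                              # redraw guard (backstop)
    low <- areaHa < config$xmin
    if (!any(low)) break
    areaHa[low] <- rPareto(sum(low), config$xmin, config$alphaTrue) *
      exp(eff[low])
  }
  areaHa[areaHa < config$xmin] <- config$xmin
  area <- areaHa * 1e4

  s <- 1 + stats::rlnorm(n, config$shapeLognormal[["mu"]],
                         config$shapeLognormal[["sigma"]])
  per <- s * 2 * sqrt(pi * area)
  fl <- rbind(c(ox, oy + H / 2), c(ox + W, oy + H / 2))
  patchSet(data.frame(id = sprintf("p%04d", seq_len(n)), x = cx, y = cy,
                      area = area, perimeter = per),
           flightline = fl)
}

#' Generate a complete synthetic landscape
#'
#' Static fields, climate cubes for the requested variables, and the patch
#' set, all derived from the single config seed. This is the stand-in for
#' the study's aerial-survey patch table and AWAP/SRTM/MODIS rasters used
#' throughout the package's tests; it emulates their statistical structure,
#' not their actual values.
#'
#' @param config a [syntheticConfig()].
#' @param variables climate variables to generate (default: those named in
#'   the effect maps).
#' @return list with `fields`, `cubes`, `patches`, `config`.
#' @export
generateLandscape <- function(config = syntheticConfig(),
                              variables = NULL) {
  if (is.null(variables))
    variables <- intersect(climateVariables(),
                           unique(c(names(config$sizeEffects),
                                    names(config$densityEffects))))
  fields <- generateStaticFields(config)
  cubes <- stats::setNames(
    lapply(variables, function(v) generateClimateCube(config, v)),
    variables)
  patches <- generatePatches(config, fields, cubes)
  list(fields = fields, cubes = cubes, patches = patches, config = config)
}
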