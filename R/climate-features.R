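#' Create a ClimateCube
#'
#' @param variable climate variable name (see [climateVariables()]).
#' @param values 3-D array `[row, col, month]`, months January of
#'   `startYear` onward in whole years.
#' @param xll,yll,cellSize grid geometry (m); the study's meteorological
#'   surfaces are ~5-km cells.
#' @param startYear first calendar year.
#' @param metadata free-form provenance list.
#' @return a [ClimateCube-class].
#' @export
climateCube <- function(variable, values, xll = 0, yll = 0, cellSize = 5000,
                        startYear = 1975L, metadata = list()) {
  new("ClimateCube", variable = variable, xll = xll, yll = yll,
      cellSize = cellSize, startYear = as.integer(startYear),
      values = values, metadata = metadata)
}

#' Temporal grains and extents
#'
#' The four temporal grains aggregate the monthly series over the months of
#' a labelled water year `Y` (March of `Y-1` through February of `Y`):
#' `FEB` (the single dieback month), `DJF` (summer, Dec-Feb), `SONDJF`
#' (spring+summer, Sep-Feb, 6 months inclusive) and `WATER_YEAR` (Mar-Feb).
#' The five extents express the drought year against the 1975-2011 record:
#' `HISTORIC` (mean over all years), `CURRENT` (the 2010/11 value),
#' `PERCENT` (current as % of historic), `ANOMALY` (current - historic) and
#' `COVARIATE` (current and historic as two columns).
#'
#' @return character vector of grain / extent names.
#' @export
temporalGrains <- function() c("FEB", "DJF", "SONDJF", "WATER_YEAR")

#' @rdname temporalGrains
#' @export
temporalExtents <- function()
  c("HISTORIC", "CURRENT", "PERCENT", "ANOMALY", "COVARIATE")

grainMonths <- function(grain, waterYear) {
  grain <- match.arg(grain, temporalGrains())
  switch(grain,
    FEB = data.frame(year = waterYear, month = 2L),
    DJF = data.frame(year = c(waterYear - 1L, waterYear, waterYear),
                     month = c(12L, 1L, 2L)),
    SONDJF = data.frame(year = c(rep(waterYear - 1L, 4L), waterYear,
                                 waterYear),
                        month = c(9L, 10L, 11L, 12L, 1L, 2L)),
    WATER_YEAR = data.frame(
      year = c(rep(waterYear - 1L, 10L), waterYear, waterYear),
      month = c(3:12, 1L, 2L)))
}

monthLayer <- function(cube, year, month) {
  idx <- (year - cube@startYear) * 12L + month
  if (idx < 1L || idx > dim(cube@values)[3L]) return(NULL)
  cube@values[, , idx]
}

#' Aggregate a climate cube over a temporal grain
#'
#' Flux variables (precipitation, PET, AET, PET-AET) are *summed* over the
#' grain's months; state variables (t_min, t_max, AET/PET) are *averaged*.
#' Water year `Y` runs March of `Y-1` through February of `Y`.
#'
#' @param cube a [ClimateCube-class].
#' @param grain one of [temporalGrains()].
#' @param waterYear water-year label (the drought year 2010/11 is 2011).
#' @return a [RasterGrid-class] of the aggregate on the cube's grid.
#' @export
aggregateGrain <- function(cube, grain, waterYear) {
  mons <- grainMonths(grain, waterYear)
  layers <- vector("list", nrow(mons))
  for (i in seq_len(nrow(mons))) {
    lay <- monthLayer(cube, mons$year[i], mons$month[i])
    if (is.null(lay))
      stop("missing month(s) for water year ", waterYear, ": ",
           paste(sprintf("%d-%02d", mons$year, mons$month), collapse = ", "),
           call. = FALSE)
    layers[[i]] <- lay
  }
  agg <- Reduce(`+`, layers)
  if (!isFluxVariable(cube@variable)) agg <- agg / length(layers)
  rasterGrid(agg, xll = cube@xll, yll = cube@yll, cellSize = cube@cellSize)
}

#' Water-year labels fully covered by a cube for a grain
#'
#' @inheritParams aggregateGrain
#' @return integer vector of water-year labels.
#' @export
availableWaterYears <- function(cube, grain) {
  ys <- yearSpan(cube)
  first <- if (grain == "FEB") ys[1L] else ys[1L] + 1L
  seq.int(first, ys[2L])
}

#' Compose a temporal extent from current and historic aggregates
#'
#' @param current [RasterGrid-class] aggregate of the drought water year.
#' @param historic list of [RasterGrid-class] aggregates, one per historic
#'   water year.
#' @param extent one of [temporalExtents()].
#' @return named list of one [RasterGrid-class] (two for `COVARIATE`:
#'   `current` and `historic`). `PERCENT` cells with zero historic mean are
#'   NA (undefined) with a warning.
#' @export
composeExtent <- function(current, historic, extent) {
  extent <- match.arg(extent, temporalExtents())
  if (!length(historic)) stop("historic span is empty", call. = FALSE)
  hmean <- Reduce(`+`, lapply(historic, gridValues)) / length(historic)
  geom <- function(v) rasterGrid(v, xll = current@xll, yll = current@yll,
                                 cellSize = current@cellSize)
  switch(extent,
    HISTORIC = list(historic = geom(hmean)),
    CURRENT = list(current = current),
    PERCENT = {
      v <- 100 * gridValues(current) / hmean
      if (any(hmean == 0)) {
        v[hmean == 0] <- NA_real_
        warning("PERCENT undefined where the historic mean is 0",
                call. = FALSE)
      }
      list(percent = geom(v))
    },
    ANOMALY = list(anomaly = geom(gridValues(current) - hmean)),
    COVARIATE = list(current = current, historic = geom(hmean)))
}

#' Enumerate the factorial temporal parameterizations
#'
#' All 20 grain x extent combinations in deterministic order: grains outer
#' (FEB, DJF, SONDJF, WATER_YEAR), extents inner (HISTORIC, CURRENT,
#' PERCENT, ANOMALY, COVARIATE). The COVARIATE extent yields two predictor
#' columns; all others one.
#'
#' @return data frame with columns `grain`, `extent`, `nColumns`.
#' @export
enumerateParameterizations <- function() {
  g <- temporalGrains(); e <- temporalExtents()
  out <- data.frame(grain = rep(g, each = length(e)),
                    extent = rep(e, times = length(g)),
                    stringsAsFactors = FALSE)
  out$nColumns <- ifelse(out$extent == "COVARIATE", 2L, 1L)
  out
}

#' Sample a raster or feature grid at patch centroids
#'
#' Value of the containing cell, no interpolation (patches are attributed
#' with the pixel value at the centroid location).
#'
#' @param grid a [RasterGrid-class] (or [StaticRaster-class]).
#' @param patches a [PatchSet-class]; every centroid must fall inside the
#'   grid extent.
#' @return numeric vector, one value per patch in patch order.
#' @export
sampleAtCentroids <- function(grid, patches) {
  p <- patchData(patches)
  valueAtPoints(grid, p$x, p$y, outside = "error", ids = p$id)
}

#' Per-patch predictor columns for one temporal parameterization
#'
#' Aggregates the cube at the given grain for the drought water year and for
#' every available historic year, composes the extent, and samples the
#' result at the patch centroids. Column names are
#' `<variable>_<grain>_<extent>` (the COVARIATE pair adds `_current` /
#' `_historic` suffixes). Temperature variables under `PERCENT` draw a
#' warning, since a %-of-historic scale is ill-behaved around 0 degrees.
#'
#' @param cube a [ClimateCube-class].
#' @param grain,extent temporal parameterization.
#' @param patches a [PatchSet-class].
#' @param currentYear drought water-year label (default 2011 = 2010/11).
#' @return data frame of one or two numeric columns, `nPatches(patches)`
#'   rows.
#' @export
climateFeature <- function(cube, grain, extent, patches,
                           currentYear = 2011L) {
  comp <- featureRasters(cube, grain, extent, currentYear)
  cols <- lapply(comp, sampleAtCentroids, patches = patches)
  base <- paste(cube@variable, tolower(grain), tolower(extent), sep = "_")
  names(cols) <- if (length(cols) == 1L) base
    else paste(base, names(comp), sep = "_")
  as.data.frame(cols)
}

#' Feature rasters for one temporal parameterization
#'
#' The raster-level counterpart of [climateFeature()]: the composed extent
#' on the cube's own grid, before sampling at centroids. The historic mean
#' is taken over every water-year label the record covers *except* the
#' current (drought) year, so anomalies measure a true departure from the
#' pre-drought record.
#'
#' @inheritParams climateFeature
#' @return named list of one or two [RasterGrid-class] objects.
#' @export
featureRasters <- function(cube, grain, extent, currentYear = 2011L) {
  if (extent == "PERCENT" && cube@variable %in% c("t_min", "t_max"))
    warning("PERCENT extent on a temperature variable: interpret with care",
            call. = FALSE)
  cur <- aggregateGrain(cube, grain, currentYear)
  histYears <- setdiff(availableWaterYears(cube, grain), currentYear)
  hist <- lapply(histYears, function(yy) aggregateGrain(cube, grain, yy))
  composeExtent(cur, hist, extent)
}
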