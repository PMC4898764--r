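#' Accessors for droughtgaps S4 containers
#'
#' Small accessor layer over the package's S4 classes so user code never
#' touches slots directly.
#'
#' @param x,object a droughtgaps S4 object.
#' @param ... passed on to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("patchData", function(x, ...) standardGeneric("patchData"))

#' @rdname accessors
#' @export
setGeneric("nPatches", function(x) standardGeneric("nPatches"))

#' @rdname accessors
#' @param unit `"m2"` or `"ha"`.
#' @export
setGeneric("patchAreas", function(x, unit = c("ha", "m2"))
  standardGeneric("patchAreas"))

#' @rdname accessors
#' @export
setGeneric("flightline", function(x) standardGeneric("flightline"))

#' @rdname accessors
#' @param name attribute (column) name.
#' @export
setGeneric("patchAttr", function(x, name) standardGeneric("patchAttr"))

#' @rdname accessors
#' @param value replacement attribute vector (length `nPatches(x)`).
#' @export
setGeneric("patchAttr<-", function(x, name, value)
  standardGeneric("patchAttr<-"))

#' @rdname accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname accessors
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))

#' @rdname accessors
#' @export
setGeneric("gridExtent", function(x) standardGeneric("gridExtent"))

#' @rdname accessors
#' @export
setGeneric("coefTable", function(x) standardGeneric("coefTable"))

#' @rdname accessors
#' @export
setGeneric("modelAIC", function(x) standardGeneric("modelAIC"))

#' @rdname accessors
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))

## ---- PatchSet methods -----------------------------------------------------

#' @rdname accessors
#' @export
setMethod("patchData", "PatchSet", function(x, ...) x@patches)

#' @rdname accessors
#' @export
setMethod("nPatches", "PatchSet", function(x) nrow(x@patches))

#' @rdname accessors
#' @export
setMethod("patchAreas", "PatchSet", function(x, unit = c("ha", "m2")) {
  unit <- match.arg(unit)
  a <- x@patches$area
  if (unit == "ha") a / 1e4 else a
})

#' @rdname accessors
#' @export
setMethod("flightline", "PatchSet", function(x) x@flightline)

#' @rdname accessors
#' @export
setMethod("patchAttr", "PatchSet", function(x, name) {
  if (!name %in% names(x@patches))
    stop("no patch attribute '", name, "'", call. = FALSE)
  x@patches[[name]]
})

#' @rdname accessors
#' @export
setReplaceMethod("patchAttr", "PatchSet", function(x, name, value) {
  stopifnot(length(value) == nrow(x@patches))
  x@patches[[name]] <- value
  validObject(x)
  x
})

setMethod("show", "PatchSet", function(object) {
  cat("PatchSet with", nrow(object@patches), "patches [unit: m]\n")
  if (nrow(object@patches)) {
    a <- object@patches$area / 1e4
    cat(sprintf("  area (ha): %.2f-%.2f (mean %.2f)\n",
                min(a), max(a), mean(a)))
  }
  extra <- setdiff(names(object@patches),
                   c("id", "x", "y", "area", "perimeter"))
  if (length(extra))
    cat("  attributes:", paste(extra, collapse = ", "), "\n")
  if (!is.null(object@flightline)) cat("  flightline: yes\n")
})

## ---- RasterGrid methods ---------------------------------------------------

#' @rdname accessors
#' @export
setMethod("gridValues", "RasterGrid", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("cellSize", "RasterGrid", function(x) x@cellSize)

#' @rdname accessors
#' @export
setMethod("gridExtent", "RasterGrid", function(x) {
  c(xmin = x@xll, xmax = x@xll + ncol(x@values) * x@cellSize,
    ymin = x@yll, ymax = x@yll + nrow(x@values) * x@cellSize)
})

setMethod("show", "RasterGrid", function(object) {
  cat(class(object), ": ", nrow(object@values), " x ", ncol(object@values),
      " cells of ", object@cellSize, " m\n", sep = "")
  rng <- range(object@values, na.rm = TRUE)
  cat(sprintf("  values: [%.4g, %.4g]\n", rng[1], rng[2]))
  if (is(object, "DensitySurface"))
    cat("  quartic kernel, bandwidth", object@bandwidth, "m",
        "(patches/km^2)\n")
  if (is(object, "StaticRaster")) cat("  variable:", object@name, "\n")
})

## ---- PowerLawFit methods --------------------------------------------------

#' @rdname accessors
#' @export
setGeneric("exponent", function(x) standardGeneric("exponent"))

#' @rdname accessors
#' @export
setMethod("exponent", "PowerLawFit", function(x) x@alpha)

#' @rdname accessors
#' @export
setGeneric("ksD", function(x) standardGeneric("ksD"))

#' @rdname accessors
#' @export
setMethod("ksD", "PowerLawFit", function(x) x@ksD)

#' @rdname accessors
#' @export
setGeneric("gofPValue", function(x) standardGeneric("gofPValue"))

#' @rdname accessors
#' @export
setMethod("gofPValue", "PowerLawFit", function(x) x@pValue)

setMethod("show", "PowerLawFit", function(object) {
  cat(sprintf("Continuous power law: alpha = %.4f (xmin = %g ha, n = %d)\n",
              object@alpha, object@xmin, object@n))
  cat(sprintf("  loglik = %.3f, KS D = %s\n", object@loglik,
              ifelse(is.na(object@ksD), "not computed",
                     sprintf("%.4f", object@ksD))))
  if (!is.na(object@pValue))
    cat(sprintf("  bootstrap p = %.3f (%d replicates, seed %d)\n",
                object@pValue, as.integer(object@nBoot),
                as.integer(object@seed)))
})

## ---- ClimateCube methods --------------------------------------------------

#' @rdname accessors
#' @export
setGeneric("climateVariable", function(x) standardGeneric("climateVariable"))

#' @rdname accessors
#' @export
setMethod("climateVariable", "ClimateCube", function(x) x@variable)

#' @rdname accessors
#' @export
setGeneric("yearSpan", function(x) standardGeneric("yearSpan"))

#' @rdname accessors
#' @export
setMethod("yearSpan", "ClimateCube", function(x) {
  c(x@startYear, x@startYear + dim(x@values)[3L] %/% 12L - 1L)
})

setMethod("show", "ClimateCube", function(object) {
  d <- dim(object@values)
  ys <- yearSpan(object)
  cat("ClimateCube '", object@variable, "': ", d[1], " x ", d[2],
      " cells of ", object@cellSize, " m, monthly ", ys[1], "-", ys[2],
      "\n", sep = "")
})

## ---- GlmFit methods -------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("coefTable", "GlmFit", function(x) x@terms)

#' @rdname accessors
#' @export
setMethod("modelAIC", "GlmFit", function(x) x@aic)

#' @rdname accessors
#' @export
setMethod("rSquared", "GlmFit", function(x) x@rSquared)

#' @rdname accessors
#' @export
setMethod("residuals", "GlmFit", function(object, ...) object@residuals)

setMethod("show", "GlmFit", function(object) {
  cat("Gaussian GLM of", object@response, "(n =", object@n, ")\n")
  tt <- object@terms
  tt$coefficient <- signif(tt$coefficient, 4)
  tt$SE <- signif(tt$SE, 4)
  tt$t <- round(tt$t, 3)
  tt$p <- signif(tt$p, 3)
  print(tt, row.names = FALSE)
  cat(sprintf("AIC = %.2f, R^2 = %.3f\n", object@aic, object@rSquared))
})
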