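#' Read a pipeline run configuration
#'
#' A single declarative YAML or JSON file; defaults match the study's
#' printed choices (xmin 0.3 ha, 2-km kernel bandwidth, 30-m density cells,
#' delta-AIC 2.0, |r| 0.7 collinearity flag). A seed is mandatory because
#' the bootstrap and Mantel stages are stochastic.
#'
#' @param path YAML/JSON file, or NULL for pure defaults plus `...`.
#' @param ... named overrides.
#' @return a named list of settings.
#' @export
runConfig <- function(path = NULL, ...) {
  defaults <- list(patch_table = NULL, patch_polygons = NULL,
                   flightline = NULL, xmin = 0.3, bandwidth = 2000,
                   cell_size = 30, delta_aic = 2.0,
                   collinearity_threshold = 0.7, n_boot = 1000,
                   n_perm = 999, seed = NULL, out_dir = "results")
  cfg <- defaults
  if (!is.null(path)) {
    file <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    cfg[names(file)] <- file
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  if (is.null(cfg$seed)) stop("config must set a seed", call. = FALSE)
  cfg
}

writeManifest <- function(cfg, outDir, inputs = character()) {
  cfgTmp <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, cfgTmp, auto_unbox = TRUE, null = "null")
  sums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(
    package = "droughtgaps",
    version = as.character(utils::packageVersion("droughtgaps")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfgTmp)),
    input_md5 = sums)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Run the patch-statistics stage
#'
#' The environmental-data-free half of the analysis: per-patch shape
#' indices, the patch-size summary, the maximum-likelihood power-law fit
#' with KS D and bootstrap adequacy p, the quartic kernel-density surface
#' and per-patch density attributes, and a log-log size histogram table.
#' All outputs land in `cfg$out_dir` as plain text (CSV / ESRI ASCII / JSON
#' manifest).
#'
#' @param patches a [PatchSet-class] (pass `patches`), or set
#'   `cfg$patch_table` / `cfg$patch_polygons` to read from file.
#' @param cfg a [runConfig()].
#' @return (invisibly) list with `patches` (attributed), `sizes`, `shape`,
#'   `fit`, `surface`, `normality`.
#' @export
runPatchStage <- function(cfg, patches = NULL) {
  inputs <- character()
  if (is.null(patches)) {
    if (!is.null(cfg$patch_table)) {
      patches <- readPatchTable(cfg$patch_table)
      inputs <- cfg$patch_table
    } else if (!is.null(cfg$patch_polygons)) {
      patches <- readPatchPolygons(cfg$patch_polygons)
      inputs <- cfg$patch_polygons
    } else stop("patch stage: no patch input configured", call. = FALSE)
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  withStage <- function(stage, expr)
    tryCatch(expr, error = function(e)
      stop("[", stage, "] ", conditionMessage(e), call. = FALSE))

  p <- patchData(patches)
  si <- withStage("shape", shapeIndex(p$area, p$perimeter))
  patchAttr(patches, "shape_index") <- si

  sizes <- withStage("size-summary", summarizeSizes(patches))
  a <- patchAreas(patches, "ha")
  fit <- withStage("power-law", fitPowerLaw(a, xmin = cfg$xmin))
  fit <- withStage("bootstrap",
                   bootstrapGof(fit, a, nBoot = cfg$n_boot, seed = cfg$seed))
  norm <- withStage("normality", normalityScreen(a))

  surface <- withStage("density",
                       kernelDensity(patches, bandwidth = cfg$bandwidth,
                                     cellSize = cfg$cell_size))
  patches <- withStage("density", attributeDensity(patches, surface))

  shapeSummary <- data.frame(metric = "shape_index", n = length(si),
                             mean = mean(si), sd = stats::sd(si),
                             min = min(si), max = max(si))
  out <- cfg$out_dir
  utils::write.csv(data.frame(n = sizes$n, mean_ha = sizes$mean,
                              sd_ha = sizes$sd, min_ha = sizes$min,
                              max_ha = sizes$max),
                   file.path(out, "size_summary.csv"), row.names = FALSE)
  utils::write.csv(shapeSummary, file.path(out, "shape_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(xmin = fit@xmin, alpha = fit@alpha,
                              n_tail = fit@n, loglik = fit@loglik,
                              ks_D = fit@ksD, boot_p = fit@pValue,
                              ks_ref_p = ksReferenceP(fit),
                              shapiro_W = norm$statistic,
                              shapiro_p = norm$p),
                   file.path(out, "power_law_fit.csv"), row.names = FALSE)
  utils::write.csv(sizeHistogram(a, xmin = cfg$xmin),
                   file.path(out, "size_histogram.csv"), row.names = FALSE)
  writePatchTable(patches, file.path(out, "patches_attributed.csv"))
  writeAsciiGrid(surface, file.path(out, "density_surface.asc"))
  writeManifest(cfg, out, inputs)
  invisible(list(patches = patches, sizes = sizes, fit = fit,
                 surface = surface, normality = norm,
                 shape = shapeSummary))
}

#' Run the environmental-association stage
#'
#' For each log-transformed patch characteristic (size, shape index,
#' kernel density): select every climate variable's temporal
#' parameterization by minimum AIC, assemble the candidate set (selected
#' climate features, static covariates at centroids, distance to the
#' flightline), screen collinearity, run forward stepwise entry under the
#' delta-AIC rule, and check residual spatial structure (coordinate
#' correlations and a Mantel test). Writes, per response, the 20-row
#' selection table, the final model (term/coefficient/SE/t/p with AIC and
#' R^2 footer), the stepwise trace, and the diagnostics.
#'
#' @param cfg a [runConfig()].
#' @param patchStage result of [runPatchStage()].
#' @param cubes named list of [ClimateCube-class] objects.
#' @param fields named list of [StaticRaster-class] objects.
#' @param responses subset of `c("size", "shape", "density")`.
#' @return (invisibly) named list per response: `selected`, `step`,
#'   `diagnostics`, `screen`.
#' @export
runAssociationStage <- function(cfg, patchStage, cubes, fields,
                                responses = c("size", "shape", "density")) {
  if (!length(cubes) && !length(fields))
    stop("association stage needs climate cubes and/or static rasters; ",
         "generateLandscape() can provide synthetic ones", call. = FALSE)
  patches <- patchStage$patches
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  respValues <- list(
    size = patchAreas(patches, "ha"),
    shape = patchAttr(patches, "shape_index"),
    density = patchAttr(patches, "kernel_density"))
  results <- list()
  for (resp in responses) {
    y <- logTransformResponse(respValues[[resp]])
    ## per-variable temporal parameterization, re-selected per response
    selected <- list()
    candidates <- list()
    selTables <- list()
    for (v in names(cubes)) {
      sel <- suppressWarnings(selectParameterization(y, cubes[[v]], patches))
      selected[[v]] <- sel
      candidates[[paste(v, tolower(sel$grain), tolower(sel$extent),
                        sep = "_")]] <- sel$features
      tab <- sel$table
      tab$variable <- v
      selTables[[v]] <- tab
    }
    for (f in names(fields))
      candidates[[f]] <- sampleAtCentroids(fields[[f]], patches)
    if (!is.null(flightline(patches))) {
      p <- patchData(patches)
      candidates[["dist_flightline"]] <-
        distanceToPolyline(p$x, p$y, flightline(patches))
    }
    screen <- withCallingHandlers(
      collinearityScreen(as.data.frame(lapply(candidates, function(b)
        if (NCOL(b) == 1L) as.numeric(unlist(b)) else b[[1L]])),
        threshold = cfg$collinearity_threshold),
      warning = function(w) invokeRestart("muffleWarning"))
    step <- stepwiseSelect(y, candidates, deltaAic = cfg$delta_aic,
                           response = paste0("log_", resp))
    diag <- residualSpatialCheck(step$fit, patches, nPerm = cfg$n_perm,
                                 seed = cfg$seed)
    ## reports
    if (length(selTables))
      utils::write.csv(do.call(rbind, selTables),
                       file.path(out, paste0("param_selection_", resp,
                                             ".csv")), row.names = FALSE)
    tt <- coefTable(step$fit)
    footer <- data.frame(term = c("AIC", "R2"),
                         coefficient = c(modelAIC(step$fit),
                                         rSquared(step$fit)),
                         SE = NA, t = NA, p = NA)
    utils::write.csv(rbind(tt, footer),
                     file.path(out, paste0("final_model_", resp, ".csv")),
                     row.names = FALSE)
    utils::write.csv(step$trace,
                     file.path(out, paste0("stepwise_trace_", resp,
                                           ".csv")), row.names = FALSE)
    utils::write.csv(as.data.frame(diag[c("xCor", "xP", "yCor", "yP",
                                          "mantelR", "mantelP")]),
                     file.path(out, paste0("diagnostics_", resp, ".csv")),
                     row.names = FALSE)
    results[[resp]] <- list(selected = selected, step = step,
                            diagnostics = diag, screen = screen)
  }
  invisible(results)
}
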