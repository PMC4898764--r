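#' Construct a PatchSet
#'
#' @param patches data frame with columns id, x, y, area, perimeter (plus any
#'   numeric attribute columns). `id` is coerced to character; if absent, row
#'   numbers are used.
#' @param polygons named list of ring coordinate matrices keyed by patch id.
#' @param flightline optional polyline coordinate matrix (m).
#' @return a validated [PatchSet-class].
#' @export
patchSet <- function(patches, polygons = list(), flightline = NULL) {
  patches <- as.data.frame(patches)
  if (!"id" %in% names(patches))
    patches$id <- as.character(seq_len(nrow(patches)))
  patches$id <- as.character(patches$id)
  core <- c("id", "x", "y", "area", "perimeter")
  patches <- patches[, c(core, setdiff(names(patches), core)), drop = FALSE]
  if (!is.null(flightline)) flightline <- as.matrix(flightline)
  new("PatchSet", patches = patches, polygons = polygons,
      flightline = flightline, unit = "m")
}

defaultPatchSchema <- function() {
  c(x = "x", y = "y", area = "area", perimeter = "perimeter", id = "id")
}

#' Read a patch table (CSV)
#'
#' Reads a comma-delimited table of patch centroid coordinates (m, projected),
#' areas (m^2) and perimeters (m) into a [PatchSet-class]. Column names are
#' mapped through `schema`; when none of the mapped names is present the
#' reader falls back to positional order (x, y, area, perimeter). Rows that
#' violate the record invariants (non-positive area/perimeter, isoperimetric
#' bound `perimeter >= 2*sqrt(pi*area)` beyond a 1e-9 relative tolerance,
#' which flags unit mismatches) are collected and reported together by row
#' number, never silently dropped.
#'
#' @param path CSV file path.
#' @param schema named character vector mapping roles `x`, `y`, `area`,
#'   `perimeter` (and optionally `id`) to column names in the file.
#' @return a [PatchSet-class].
#' @export
readPatchTable <- function(path, schema = defaultPatchSchema()) {
  raw <- utils::read.csv(path, check.names = FALSE)
  roles <- c("x", "y", "area", "perimeter")
  have <- vapply(roles, function(r)
    !is.na(schema[r]) && schema[r] %in% names(raw), logical(1))
  if (!any(have)) {
    if (ncol(raw) < 4L)
      stop("patch table needs at least 4 columns (x, y, area, perimeter)")
    cols <- stats::setNames(names(raw)[1:4], roles)   # positional fallback
  } else if (all(have)) {
    cols <- schema[roles]
  } else {
    stop("schema error: mapped column(s) missing from file: ",
         paste(schema[roles][!have], collapse = ", "), call. = FALSE)
  }
  df <- data.frame(x = as.numeric(raw[[cols["x"]]]),
                   y = as.numeric(raw[[cols["y"]]]),
                   area = as.numeric(raw[[cols["area"]]]),
                   perimeter = as.numeric(raw[[cols["perimeter"]]]))
  idcol <- schema["id"]
  df$id <- if (!is.na(idcol) && idcol %in% names(raw))
    as.character(raw[[idcol]]) else as.character(seq_len(nrow(df)))

  probs <- character()
  bad <- which(!is.finite(df$area) | !is.finite(df$perimeter) |
                 df$area <= 0 | df$perimeter <= 0)
  if (length(bad))
    probs <- c(probs, paste0("row ", bad,
                             ": non-positive or non-numeric area/perimeter"))
  ok <- setdiff(seq_len(nrow(df)), bad)
  iso <- ok[df$perimeter[ok] < 2 * sqrt(pi * df$area[ok]) * (1 - 1e-9)]
  if (length(iso))
    probs <- c(probs, paste0("row ", iso,
                             ": perimeter below the isoperimetric bound ",
                             "(check units)"))
  if (length(probs))
    stop("invalid patch records:\n  ", paste(probs, collapse = "\n  "),
         call. = FALSE)
  if (nrow(df) && looksGeographic(df$x, df$y))
    stop("coordinates look geographic (degrees); reproject to a metre-based ",
         "system before reading", call. = FALSE)
  patchSet(df[, c("id", "x", "y", "area", "perimeter")])
}

#' Read patch polygons from GeoJSON
#'
#' Reads a GeoJSON FeatureCollection of simple Polygons (projected metre
#' coordinates) and derives each patch's area (shoelace formula), perimeter
#' (ring length) and area-weighted centroid. Only the outer ring of each
#' polygon is used.
#'
#' @param path GeoJSON file path.
#' @return a [PatchSet-class] with polygons attached.
#' @export
readPatchPolygons <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection")
  feats <- gj$features
  rows <- vector("list", length(feats))
  polys <- list()
  for (k in seq_along(feats)) {
    f <- feats[[k]]
    geom <- f$geometry
    if (!identical(geom$type, "Polygon"))
      stop("feature ", k, ": only Polygon geometries are supported")
    ring <- do.call(rbind, lapply(geom$coordinates[[1L]],
                                  function(pt) c(pt[[1L]], pt[[2L]])))
    if (looksGeographic(ring[, 1L], ring[, 2L]))
      stop("feature ", k, ": coordinates look geographic (degrees); ",
           "reproject to a metre-based system", call. = FALSE)
    if (isSelfIntersecting(ring))
      stop("feature ", k, ": self-intersecting ring", call. = FALSE)
    g <- ringGeometry(ring)
    id <- if (!is.null(f$properties$id)) as.character(f$properties$id)
      else as.character(k)
    rows[[k]] <- data.frame(id = id, x = g$centroid[1L], y = g$centroid[2L],
                            area = g$area, perimeter = g$perimeter)
    polys[[id]] <- closeRing(ring)
  }
  patchSet(do.call(rbind, rows), polygons = polys)
}

#' Read a flightline polyline from GeoJSON
#'
#' @param path GeoJSON file containing a LineString geometry (bare geometry,
#'   Feature, or FeatureCollection whose first feature is a LineString).
#' @return k x 2 coordinate matrix.
#' @export
readFlightline <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  geom <- switch(gj$type %||% "",
                 FeatureCollection = gj$features[[1L]]$geometry,
                 Feature = gj$geometry,
                 LineString = gj,
                 stop("no LineString found in ", path))
  if (!identical(geom$type, "LineString"))
    stop("flightline geometry must be a LineString")
  coords <- do.call(rbind, lapply(geom$coordinates,
                                  function(pt) c(pt[[1L]], pt[[2L]])))
  if (looksGeographic(coords[, 1L], coords[, 2L]))
    stop("flightline coordinates look geographic; reproject first")
  coords
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a patch table (CSV)
#'
#' Writes the full patch data frame (core fields plus attributes) with 15
#' significant digits so numeric fields round-trip through
#' [readPatchTable()] to within 1e-9.
#'
#' @param patches a [PatchSet-class].
#' @param path output CSV path.
#' @export
writePatchTable <- function(patches, path) {
  stopifnot(is(patches, "PatchSet"))
  df <- patchData(patches)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) format(v, digits = 15,
                                                scientific = FALSE,
                                                trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
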