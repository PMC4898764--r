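## Construction, point lookup and ESRI ASCII I/O for RasterGrid objects.

#' Create a RasterGrid
#'
#' @param values numeric matrix, row 1 = northern-most row.
#' @param xll,yll lower-left corner (m).
#' @param cellSize cell edge (m).
#' @return a [RasterGrid-class].
#' @export
rasterGrid <- function(values, xll = 0, yll = 0, cellSize = 30) {
  new("RasterGrid", xll = xll, yll = yll, cellSize = cellSize,
      values = values)
}

#' Row/column index of the cells containing points
#'
#' Points on the extreme north/east edge are assigned to the last cell so
#' that the closed extent is fully covered.
#'
#' @param grid a [RasterGrid-class] (or object with the same geometry slots).
#' @param x,y point coordinates (m).
#' @return data frame with columns `row`, `col`; NA outside the extent.
#' @export
cellIndexOf <- function(grid, x, y) {
  nr <- nrow(grid@values); nc <- ncol(grid@values)
  cs <- grid@cellSize
  fx <- (x - grid@xll) / cs
  fy <- (y - grid@yll) / cs
  col <- floor(fx) + 1
  rowFromS <- floor(fy) + 1
  col[fx == nc] <- nc          # closed upper edge
  rowFromS[fy == nr] <- nr
  out <- col < 1 | col > nc | rowFromS < 1 | rowFromS > nr
  col[out] <- NA_integer_
  rowFromS[out] <- NA_integer_
  data.frame(row = nr - rowFromS + 1L, col = as.integer(col))
}

#' Sample a grid at point locations
#'
#' Value of the cell containing each point; no interpolation, matching the
#' convention of attributing patches with the pixel value at their centroid.
#'
#' @inheritParams cellIndexOf
#' @param outside `"error"` (default) or `"na"` for points beyond the extent.
#' @param ids optional point labels used in error messages.
#' @return numeric vector of cell values.
#' @export
valueAtPoints <- function(grid, x, y, outside = c("error", "na"), ids = NULL) {
  outside <- match.arg(outside)
  idx <- cellIndexOf(grid, x, y)
  bad <- is.na(idx$row)
  if (any(bad) && outside == "error") {
    lab <- if (is.null(ids)) paste("point", which(bad)) else ids[bad]
    stop("points outside raster extent: ", paste(lab, collapse = ", "),
         call. = FALSE)
  }
  v <- rep(NA_real_, length(x))
  ok <- !bad
  v[ok] <- grid@values[cbind(idx$row[ok], idx$col[ok])]
  v
}

#' Read / write ESRI ASCII grids
#'
#' Plain-text raster exchange format with a six-line header (`ncols`,
#' `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by
#' rows of values, north first.
#'
#' @param path file path.
#' @return `readAsciiGrid` returns a [RasterGrid-class].
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ESRI ASCII header in ", path)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  rasterGrid(m, xll = hdr$xllcorner, yll = hdr$yllcorner,
             cellSize = hdr$cellsize)
}

#' @rdname readAsciiGrid
#' @param grid a [RasterGrid-class].
#' @param nodata value written for NA cells.
#' @export
writeAsciiGrid <- function(grid, path, nodata = -9999) {
  v <- grid@values
  v[is.na(v)] <- nodata
  hdr <- c(paste("ncols", ncol(v)), paste("nrows", nrow(v)),
           paste("xllcorner", format(grid@xll, scientific = FALSE)),
           paste("yllcorner", format(grid@yll, scientific = FALSE)),
           paste("cellsize", format(grid@cellSize, scientific = FALSE)),
           paste("NODATA_value", nodata))
  body <- apply(v, 1L, function(r)
    paste(format(r, trim = TRUE, scientific = FALSE, digits = 10),
          collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
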