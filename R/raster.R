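#' Lightweight georeferenced raster grid
#'
#' A `raster_grid` is a numeric matrix on a regular lon/lat grid together with
#' its geotransform. Row 1 is the northernmost row; column 1 the westernmost
#' column. The geotransform is stored as the lower-left corner of the grid
#' (`xll`, `yll`) plus a square cell size in decimal degrees, the convention
#' of the ESRI ASCII grid format used for on-disk exchange.
#'
#' @param values numeric matrix (row 1 = north).
#' @param xll,yll longitude/latitude of the lower-left corner, degrees.
#' @param cellsize cell size in decimal degrees (square cells).
#' @param name layer name.
#' @param nodata value written for missing cells on export; `NA` internally.
#' @return object of class `raster_grid`.
#' @export
raster_grid <- function(values, xll, yll, cellsize, name = "layer",
                        nodata = -9999) {
  values <- as.matrix(values)
  if (!is.numeric(values) && !is.logical(values))
    stop("raster values must be numeric or logical")
  if (cellsize <= 0) stop("cellsize must be positive")
  structure(
    list(values = values, xll = xll, yll = yll, cellsize = cellsize,
         name = name, nodata = nodata),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("raster_grid '%s': %d x %d cells, %.4g deg, origin (%.4g, %.4g)\n",
              x$name, nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll))
  v <- x$values[is.finite(x$values)]
  if (length(v))
    cat(sprintf("  values: min %.4g, mean %.4g, max %.4g (%d NA)\n",
                min(v), mean(v), max(v), sum(!is.finite(x$values))))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' Coordinates of cell centres
#'
#' @param grid a `raster_grid` (or any object with `xll`, `yll`, `cellsize`
#'   and a `values` matrix).
#' @return list with `lon` (length ncol) and `lat` (length nrow, north to
#'   south) of cell centres, in degrees.
#' @export
grid_coords <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  lon <- grid$xll + (seq_len(nc) - 0.5) * grid$cellsize
  lat <- grid$yll + (nr - seq_len(nr) + 0.5) * grid$cellsize
  list(lon = lon, lat = lat)
}

#' Cell centres as a two-column matrix in row-major cell order
#'
#' Cell order is the internal linear order `as.vector(values)` (column-major
#' over the matrix); every function in the package that flattens a raster
#' uses this same order.
#' @inheritParams grid_coords
#' @return matrix with columns `lon`, `lat`, one row per cell.
#' @export
grid_points <- function(grid) {
  cc <- grid_coords(grid)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  cbind(lon = rep(cc$lon, each = nr), lat = rep(cc$lat, times = nc))
}

#' Locate coordinates on the grid
#'
#' @inheritParams grid_coords
#' @param lon,lat coordinate vectors, degrees.
#' @return integer vector of linear cell indices (column-major); `NA` for
#'   points off the grid.
#' @export
cell_index <- function(grid, lon, lat) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  col <- floor((lon - grid$xll) / grid$cellsize) + 1L
  row <- nr - floor((lat - grid$yll) / grid$cellsize)
  bad <- col < 1L | col > nc | row < 1L | row > nr
  idx <- (col - 1L) * nr + row
  idx[bad] <- NA_integer_
  as.integer(idx)
}

#' Check that rasters share a grid
#' @param ... `raster_grid` objects.
#' @return `TRUE` invisibly; errors on mismatch.
#' @export
check_aligned <- function(...) {
  gs <- list(...)
  ref <- gs[[1]]
  for (g in gs[-1]) {
    if (!identical(dim(g$values), dim(ref$values)) ||
        abs(g$xll - ref$xll) > 1e-9 || abs(g$yll - ref$yll) > 1e-9 ||
        abs(g$cellsize - ref$cellsize) > 1e-12)
      stop("rasters are not aligned: '", g$name, "' vs '", ref$name, "'")
  }
  invisible(TRUE)
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text georeferenced raster interchange; readable by GDAL and most GIS
#' software.
#' @inheritParams grid_coords
#' @param path output file (conventionally `.asc`).
#' @export
write_ascii_grid <- function(grid, path) {
  v <- grid$values
  v[!is.finite(v)] <- grid$nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", grid$xll),
    sprintf("yllcorner %.10g", grid$yll),
    sprintf("cellsize %.10g", grid$cellsize),
    sprintf("NODATA_value %.10g", grid$nodata))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(v, trim = TRUE, digits = 10), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#' @param path file written by [write_ascii_grid()] or any conforming tool.
#' @param name layer name for the result.
#' @return a `raster_grid`; nodata cells become `NA`.
#' @export
read_ascii_grid <- function(path, name = sub("\\.asc$", "", basename(path))) {
  lines <- readLines(path, n = 6)
  kv <- strsplit(trimws(lines), "\\s+")
  hdr <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                         tolower(vapply(kv, `[`, "", 1)))
  v <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(v) <- NULL
  v[v == hdr[["nodata_value"]]] <- NA_real_
  raster_grid(v, hdr[["xllcorner"]], hdr[["yllcorner"]], hdr[["cellsize"]],
              name = name, nodata = hdr[["nodata_value"]])
}

#' Bilinear resampling onto a reference grid
#'
#' Any layer on a different grid must be resampled to the reference grid
#' before stacking; bilinear interpolation between the four surrounding
#' source-cell centres, clamped at the source edge.
#' @param grid source `raster_grid`.
#' @param ref reference `raster_grid` supplying the target geometry.
#' @return a `raster_grid` on `ref`'s grid.
#' @export
resample_bilinear <- function(grid, ref) {
  src <- grid$values
  nrs <- nrow(src); ncs <- ncol(src)
  scc <- grid_coords(grid)
  # source lat runs north->south; work in ascending order for interpolation
  lat_asc <- rev(scc$lat)
  src_asc <- src[nrs:1, , drop = FALSE]
  pts <- grid_points(ref)
  fx <- (pts[, "lon"] - scc$lon[1]) / grid$cellsize
  fy <- (pts[, "lat"] - lat_asc[1]) / grid$cellsize
  fx <- pmin(pmax(fx, 0), ncs - 1); fy <- pmin(pmax(fy, 0), nrs - 1)
  x0 <- pmin(floor(fx), ncs - 2); y0 <- pmin(floor(fy), nrs - 2)
  if (ncs < 2 || nrs < 2) stop("source grid too small to resample")
  wx <- fx - x0; wy <- fy - y0
  g <- function(r, c) src_asc[cbind(r + 1L, c + 1L)]
  out <- (1 - wx) * (1 - wy) * g(y0, x0) + wx * (1 - wy) * g(y0, x0 + 1) +
    (1 - wx) * wy * g(y0 + 1, x0) + wx * wy * g(y0 + 1, x0 + 1)
  raster_grid(matrix(out, nrow(ref$values), ncol(ref$values)),
              ref$xll, ref$yll, ref$cellsize, name = grid$name)
}

#' Bundle aligned layers into a predictor stack
#'
#' @param layers named list of `raster_grid` objects on a shared grid.
#' @param scenario,period provenance tags (`"current"` etc.).
#' @return object of class `predictor_stack`.
#' @export
predictor_stack <- function(layers, scenario = "current", period = "current") {
  if (is.null(names(layers)) || anyDuplicated(names(layers)))
    stop("layers must be uniquely named")
  do.call(check_aligned, unname(layers))
  structure(list(layers = layers, scenario = scenario, period = period,
                 grid = layers[[1]]),
            class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  cat(sprintf("predictor_stack [%s/%s]: %s\n", x$scenario, x$period,
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' Extract stack values as a data frame
#'
#' @param stack a `predictor_stack`.
#' @param cells optional linear cell indices; default all cells.
#' @return data.frame, one column per layer, rows in cell order.
#' @export
stack_values <- function(stack, cells = NULL) {
  out <- lapply(stack$layers, function(g) {
    v <- as.vector(g$values)
    if (is.null(cells)) v else v[cells]
  })
  as.data.frame(out)
}
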