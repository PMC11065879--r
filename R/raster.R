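# Minimal single-band raster container with plain-text ESRI ASCII grid I/O.
# Values live in a matrix (row 1 = northernmost row); the geotransform is
# lower-left corner + square cell size. Coordinates may be metres in a local
# projected frame (synthetic scenes) or degrees (EPSG:4326).

#' Single-band georeferenced raster
#'
#' @param values numeric or integer matrix; row 1 is the top (north) row.
#' @param xll,yll coordinates of the lower-left corner.
#' @param cellsize square cell size (same units as `xll`/`yll`).
#' @param crs `"local-metres"` or `"EPSG:4326"`.
#' @param nodata nodata code used on disk.
#' @return An object of class `soy_raster`.
#' @export
soy_raster <- function(values, xll = 0, yll = 0, cellsize = 10,
                       crs = "local-metres", nodata = -9999) {
  stopifnot(is.matrix(values))
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, crs = crs, nodata = nodata),
            class = "soy_raster")
}

#' @export
print.soy_raster <- function(x, ...) {
  cat("<soy_raster> ", nrow(x$values), "x", ncol(x$values), " cells, ",
      x$cellsize, "-unit cells, crs ", x$crs, "\n", sep = "")
  invisible(x)
}

#' Cell-centre coordinates of a raster
#'
#' @param r a [soy_raster()].
#' @return List with vectors `x` (per column) and `y` (per row, row 1 =
#'   north).
#' @export
raster_coords <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  list(x = r$xll + (seq_len(nc) - 0.5) * r$cellsize,
       y = r$yll + (nr - seq_len(nr) + 0.5) * r$cellsize)
}

#' Write a raster as an ESRI ASCII grid
#'
#' @param r a [soy_raster()].
#' @param path output `.asc` path.
#' @export
write_asc <- function(r, path) {
  v <- r$values
  v[is.na(v)] <- r$nodata
  hdr <- c(paste("ncols", ncol(v)), paste("nrows", nrow(v)),
           paste("xllcorner", r$xll), paste("yllcorner", r$yll),
           paste("cellsize", r$cellsize), paste("NODATA_value", r$nodata))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path `.asc` path.
#' @param crs coordinate system tag to attach.
#' @return A [soy_raster()]; nodata cells become `NA`.
#' @export
read_asc <- function(path, crs = "local-metres") {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  v <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(v) <- NULL
  v[v == h[["nodata_value"]]] <- NA
  soy_raster(v, xll = h[["xllcorner"]], yll = h[["yllcorner"]],
             cellsize = h[["cellsize"]], crs = crs,
             nodata = h[["nodata_value"]])
}

#' Eight-neighbourhood majority filter
#'
#' Each pixel takes the majority class among itself and its eight
#' neighbours; exact ties keep the centre value, and nodata neighbours are
#' excluded from the vote. Intended for a binary soybean/non-soybean map:
#' a single application removes isolated one-pixel speckle and fills
#' one-pixel holes inside homogeneous plots. Idempotent on homogeneous
#' rasters, and never introduces a class absent from a pixel's 3x3
#' neighbourhood.
#'
#' @param r a [soy_raster()] with values in `{0, 1, NA}`.
#' @return The filtered [soy_raster()].
#' @export
majority_filter <- function(r) {
  stopifnot(inherits(r, "soy_raster"))
  m <- r$values
  if (!all(m %in% c(0, 1) | is.na(m)))
    stop("majority_filter expects a binary {0,1,NA} map")
  nr <- nrow(m); nc <- ncol(m)
  ones <- matrix(0, nr, nc)
  valid <- matrix(0, nr, nc)
  pad <- matrix(NA_real_, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  for (di in 0:2) for (dj in 0:2) {
    w <- pad[di + seq_len(nr), dj + seq_len(nc)]
    ok <- !is.na(w)
    valid <- valid + ok
    w[!ok] <- 0
    ones <- ones + w
  }
  out <- m
  win <- ones > valid / 2
  lose <- ones < valid / 2
  out[win & !is.na(m)] <- 1
  out[lose & !is.na(m)] <- 0
  soy_raster(out, r$xll, r$yll, r$cellsize, r$crs, r$nodata)
}

#' Soybean area per administrative unit
#'
#' Counts soybean pixels (value 1) per unit and multiplies by the per-pixel
#' area. For `crs = "local-metres"` the pixel area is `cellsize^2`; for
#' `"EPSG:4326"` it is computed geodesically per raster row (WGS84) via
#' \pkg{geosphere}. Units are defined either by a zone raster of identical
#' shape or by a named list of polygons (two-column x/y matrices; cell
#' centres are assigned by point-in-polygon).
#'
#' @param r a [soy_raster()] soybean map (1 = soybean).
#' @param zones zone matrix (same dim, integer/character codes) or named
#'   list of polygon matrices.
#' @param unit output unit: `"m2"`, `"ha"` or `"kha"`.
#' @return Named numeric vector of areas per unit.
#' @export
pixel_area <- function(r, zones, unit = c("m2", "ha", "kha")) {
  stopifnot(inherits(r, "soy_raster"))
  unit <- match.arg(unit)
  nr <- nrow(r$values); nc <- ncol(r$values)
  if (identical(r$crs, "EPSG:4326")) {
    yc <- raster_coords(r)$y
    h <- r$cellsize
    # geodesic area of one cell in each row (cells in a row share latitude)
    row_area <- vapply(yc, function(lat) {
      geosphere::areaPolygon(rbind(c(0, lat - h / 2), c(h, lat - h / 2),
                                   c(h, lat + h / 2), c(0, lat + h / 2)))
    }, numeric(1))
    cell_area <- matrix(row_area, nr, nc)
  } else {
    cell_area <- matrix(r$cellsize^2, nr, nc)
  }
  if (is.matrix(zones)) {
    if (!all(dim(zones) == dim(r$values)))
      stop("zone matrix must match the raster dimensions")
    zvec <- as.vector(zones)
  } else {
    co <- raster_coords(r)
    gx <- matrix(co$x, nr, nc, byrow = TRUE)
    gy <- matrix(co$y, nr, nc)
    zvec <- rep(NA_character_, nr * nc)
    for (nm in names(zones)) {
      p <- zones[[nm]]
      inside <- pracma::inpolygon(as.vector(gx), as.vector(gy),
                                  p[, 1], p[, 2])
      zvec[inside] <- nm
    }
  }
  soy <- as.vector(r$values) == 1 & !is.na(as.vector(r$values))
  a <- tapply(as.vector(cell_area) * soy, zvec, sum)
  a <- stats::setNames(as.numeric(a), names(a))
  a / switch(unit, m2 = 1, ha = 1e4, kha = 1e7)
}
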