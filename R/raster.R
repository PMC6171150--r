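#' Aligned raster stack for a survey landscape
#'
#' Bundles the three covariate rasters the selection model needs --
#' categorical vegetation (original map codes 1--25), elevation (m a.s.l.) and
#' the regional empirical timberline elevation (RET, m a.s.l.) -- on a single
#' planar grid, together with slope and aspect derived from the elevation
#' raster. Coordinates are planar metric (UTM-like); row 1 is the northern
#' edge and column 1 the western edge. The grid origin is the lower-left
#' corner, as in the plain-text grid format written by [write_grid()].
#'
#' @param vegetation integer matrix of vegetation codes (1--25, or `NA`).
#' @param elevation numeric matrix, metres above sea level.
#' @param timberline numeric matrix, RET metres above sea level.
#' @param origin numeric length-2, x/y of the lower-left grid corner (m).
#' @param cellsize cell edge length in metres (> 0).
#' @param nodata sentinel used when rasters are written to disk.
#' @return An object of class `ptarmigan_landscape`: a list with the three
#'   input rasters, derived `slope_deg` and `aspect_deg` rasters, and grid
#'   metadata (`origin`, `cellsize`, `nrow`, `ncol`, `nodata`).
#' @seealso [make_landscape()] for simulated landscapes, [slope_aspect()].
#' @export
landscape_stack <- function(vegetation, elevation, timberline,
                            origin = c(0, 0), cellsize = 30,
                            nodata = -9999) {
  stopifnot(is.matrix(vegetation), is.matrix(elevation), is.matrix(timberline))
  if (!all(dim(vegetation) == dim(elevation)) ||
      !all(dim(vegetation) == dim(timberline))) {
    stop("all rasters must share one grid (identical dimensions)")
  }
  if (length(cellsize) != 1L || !is.finite(cellsize) || cellsize <= 0) {
    stop("cellsize must be a single positive number")
  }
  codes <- vegetation[!is.na(vegetation)]
  if (length(codes) && (any(codes != round(codes)) || any(codes < 1) || any(codes > 25))) {
    stop("vegetation codes must be integers in 1..25 or NA")
  }
  ls <- structure(
    list(vegetation = vegetation, elevation = elevation, timberline = timberline,
         origin = as.numeric(origin), cellsize = as.numeric(cellsize),
         nrow = nrow(vegetation), ncol = ncol(vegetation), nodata = nodata),
    class = "ptarmigan_landscape")
  terr <- slope_aspect(elevation, cellsize)
  ls$slope_deg <- terr$slope_deg
  ls$aspect_deg <- terr$aspect_deg
  ls
}

#' @export
print.ptarmigan_landscape <- function(x, ...) {
  cat(sprintf("ptarmigan_landscape: %d x %d cells @ %g m (%.1f x %.1f km)\n",
              x$nrow, x$ncol, x$cellsize,
              x$nrow * x$cellsize / 1000, x$ncol * x$cellsize / 1000))
  cat(sprintf("  vegetation codes: %s\n",
              paste(sort(unique(as.vector(x$vegetation))), collapse = " ")))
  cat(sprintf("  elevation: %.0f-%.0f m; timberline: %.0f-%.0f m\n",
              min(x$elevation), max(x$elevation),
              min(x$timberline), max(x$timberline)))
  invisible(x)
}

#' Extent of a landscape
#'
#' @param landscape a `ptarmigan_landscape`.
#' @return named numeric: `xmin`, `xmax`, `ymin`, `ymax` (m).
#' @export
landscape_extent <- function(landscape) {
  c(xmin = landscape$origin[1],
    xmax = landscape$origin[1] + landscape$ncol * landscape$cellsize,
    ymin = landscape$origin[2],
    ymax = landscape$origin[2] + landscape$nrow * landscape$cellsize)
}

#' Slope and aspect from an elevation raster (Horn's method)
#'
#' Eight-neighbour finite differences on the cell-centre grid, with edge rows
#' and columns clamped (replicated) so derived rasters keep the grid of the
#' input. Aspect is the compass bearing of the downslope direction, degrees
#' clockwise from north in `[0, 360)`; cells with zero gradient get slope 0
#' and aspect 0 ("flat").
#'
#' @param elevation numeric matrix (row 1 = north edge), metres.
#' @param cellsize cell edge length, metres.
#' @return list of matrices `slope_deg`, `aspect_deg`.
#' @export
slope_aspect <- function(elevation, cellsize) {
  nr <- nrow(elevation); nc <- ncol(elevation)
  pad <- elevation[c(1, 1:nr, nr), c(1, 1:nc, nc)]  # clamp edges
  i <- 2:(nr + 1); j <- 2:(nc + 1)
  nw <- pad[i - 1, j - 1]; n_ <- pad[i - 1, j]; ne <- pad[i - 1, j + 1]
  w_ <- pad[i,     j - 1];                      e_ <- pad[i,     j + 1]
  sw <- pad[i + 1, j - 1]; s_ <- pad[i + 1, j]; se <- pad[i + 1, j + 1]
  # gradient components in map units: x east, y north (row index runs south)
  gx <- ((ne + 2 * e_ + se) - (nw + 2 * w_ + sw)) / (8 * cellsize)
  gy <- ((nw + 2 * n_ + ne) - (sw + 2 * s_ + se)) / (8 * cellsize)
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  aspect <- (atan2(-gx, -gy) * 180 / pi) %% 360
  aspect[slope == 0] <- 0
  list(slope_deg = slope, aspect_deg = aspect)
}

#' Read / write a plain-text grid raster
#'
#' A minimal human-readable exchange format: a six-line header (`ncols`,
#' `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by
#' `nrows` whitespace-separated rows, north row first -- the layout used by
#' common GIS ASCII grids.
#'
#' @param mat numeric matrix, row 1 = north edge.
#' @param path file path.
#' @param origin lower-left corner c(x, y), metres.
#' @param cellsize cell size, metres.
#' @param nodata value substituted for `NA` on write and mapped back on read.
#' @return `read_grid` returns a list with `data` (matrix, `NA` for nodata),
#'   `origin`, `cellsize`, `nodata`.
#' @export
write_grid <- function(mat, path, origin = c(0, 0), cellsize = 30,
                       nodata = -9999) {
  stopifnot(is.matrix(mat))
  m <- mat
  m[is.na(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(m)), paste("nrows", nrow(m)),
    paste("xllcorner", format(origin[1], digits = 15)),
    paste("yllcorner", format(origin[2], digits = 15)),
    paste("cellsize", format(cellsize, digits = 15)),
    paste("NODATA_value", format(nodata, digits = 15))), con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  val <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  m <- as.matrix(utils::read.table(path, skip = 6L))
  dimnames(m) <- NULL
  stopifnot(nrow(m) == val[["nrows"]], ncol(m) == val[["ncols"]])
  m[m == val[["nodata_value"]]] <- NA
  list(data = m, origin = unname(val[c("xllcorner", "yllcorner")]),
       cellsize = unname(val[["cellsize"]]), nodata = unname(val[["nodata_value"]]))
}

#' Locate grid cells containing points
#'
#' Point-in-cell lookup (no interpolation): each point is assigned the cell
#' whose rectangle contains it. Points on an interior cell edge belong to the
#' cell to the north/east half-open convention implied by `floor`.
#'
#' @param landscape a `ptarmigan_landscape`.
#' @param x,y point coordinates (m).
#' @return list of integer vectors `row`, `col` (NA-free; errors if any point
#'   is outside the raster extent).
#' @export
cell_index <- function(landscape, x, y) {
  ext <- landscape_extent(landscape)
  bad <- x < ext["xmin"] | x > ext["xmax"] | y < ext["ymin"] | y > ext["ymax"]
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("point outside raster extent: (%.1f, %.1f)", x[i], y[i]))
  }
  col <- pmin(floor((x - ext["xmin"]) / landscape$cellsize) + 1L, landscape$ncol)
  row <- pmin(floor((ext["ymax"] - y) / landscape$cellsize) + 1L, landscape$nrow)
  list(row = as.integer(row), col = as.integer(col))
}

#' Coordinates of all cell centres
#'
#' @param landscape a `ptarmigan_landscape`.
#' @return data.frame with `row`, `col`, `x`, `y` in row-major order.
#' @export
cell_centres <- function(landscape) {
  ext <- landscape_extent(landscape)
  cs <- landscape$cellsize
  row <- rep(seq_len(landscape$nrow), each = landscape$ncol)
  col <- rep(seq_len(landscape$ncol), times = landscape$nrow)
  data.frame(row = row, col = col,
             x = ext[["xmin"]] + (col - 0.5) * cs,
             y = ext[["ymax"]] - (row - 0.5) * cs)
}
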