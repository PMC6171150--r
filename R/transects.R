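#' Lay out systematic parallel transects over a landscape
#'
#' Places straight survey lines at a fixed spacing following the map grid, the
#' design used by the national line-transect programme (500-m interval,
#' north--south or east--west bearing). Lines run the full extent of the
#' landscape and are grouped into survey areas by partitioning the extent into
#' equal strips perpendicular to the lines, so every line belongs to exactly
#' one area.
#'
#' Boundary convention: lines sit at `min + k * spacing` for
#' `k = 0, 1, ...` while the position stays within the extent, so both edges
#' carry a line when the spacing divides the extent exactly (spacing equal to
#' the extent width gives 2 lines), and a spacing wider than the extent still
#' returns the single line on the low edge.
#'
#' @param landscape a `ptarmigan_landscape` (only its extent is used).
#' @param spacing_m distance between neighbouring lines, metres (> 0).
#' @param bearing `"NS"` for north--south lines, `"EW"` for east--west.
#' @param n_areas number of survey areas (strips across the line positions).
#' @param inset_m margin inset from the landscape edge (m); use at least the
#'   buffer half-width when line-buffers must stay inside the raster.
#' @return An object of class `transect_set`: list with
#'   * `lines`: named list of 2-column vertex matrices (x, y in metres);
#'   * `info`: data.frame with `transect_id`, `area_id`, `length_km`.
#' @export
layout_transects <- function(landscape, spacing_m = 500,
                             bearing = c("NS", "EW"), n_areas = 4,
                             inset_m = 0) {
  bearing <- match.arg(bearing)
  if (spacing_m <= 0) stop("spacing_m must be positive")
  ext <- landscape_extent(landscape)
  ext <- c(xmin = ext[["xmin"]] + inset_m, xmax = ext[["xmax"]] - inset_m,
           ymin = ext[["ymin"]] + inset_m, ymax = ext[["ymax"]] - inset_m)
  if (ext[["xmax"]] <= ext[["xmin"]] || ext[["ymax"]] <= ext[["ymin"]]) {
    stop("inset_m leaves no interior extent")
  }
  if (bearing == "NS") {
    lo <- ext[["xmin"]]; hi <- ext[["xmax"]]
    span <- c(ext[["ymin"]], ext[["ymax"]])
  } else {
    lo <- ext[["ymin"]]; hi <- ext[["ymax"]]
    span <- c(ext[["xmin"]], ext[["xmax"]])
  }
  pos <- seq(lo, hi + 1e-9, by = spacing_m)
  n <- length(pos)
  width <- hi - lo
  strip <- if (width > 0) {
    pmin(floor((pos - lo) / width * n_areas) + 1L, n_areas)
  } else rep(1L, n)
  ids <- sprintf("T%03d", seq_len(n))
  lines <- vector("list", n)
  for (i in seq_len(n)) {
    lines[[i]] <- if (bearing == "NS") {
      cbind(x = c(pos[i], pos[i]), y = span)
    } else {
      cbind(x = span, y = c(pos[i], pos[i]))
    }
  }
  names(lines) <- ids
  info <- data.frame(
    transect_id = ids,
    area_id = sprintf("A%02d", strip),
    length_km = rep(abs(diff(span)) / 1000, n),
    stringsAsFactors = FALSE)
  structure(list(lines = lines, info = info), class = "transect_set")
}

#' @export
print.transect_set <- function(x, ...) {
  cat(sprintf("transect_set: %d lines, %d survey areas, %.1f km total\n",
              nrow(x$info), length(unique(x$info$area_id)),
              sum(x$info$length_km)))
  invisible(x)
}

#' Transect polyline length in kilometres
#'
#' @param verts 2-column matrix of polyline vertices (m).
#' @return length in km.
#' @export
polyline_length_km <- function(verts) {
  if (nrow(verts) < 2) stop("polyline needs at least 2 vertices")
  sum(sqrt(rowSums(diff(verts)^2))) / 1000
}

#' Build a survey table for repeated visits to each transect
#'
#' One survey event per transect and year, with effort equal to the transect
#' length (the whole line is walked at each visit).
#'
#' @param transects a `transect_set`.
#' @param years integer vector of survey years (default the 2014--2017
#'   programme window).
#' @return data.frame with `survey_id`, `transect_id`, `area_id`, `year`,
#'   `effort_km`; `survey_id` is unique per row.
#' @export
survey_table <- function(transects, years = 2014:2017) {
  info <- transects$info
  g <- expand.grid(transect_id = info$transect_id, year = years,
                   stringsAsFactors = FALSE)
  g <- g[order(g$transect_id, g$year), ]
  g$area_id <- info$area_id[match(g$transect_id, info$transect_id)]
  g$effort_km <- info$length_km[match(g$transect_id, info$transect_id)]
  g$survey_id <- sprintf("%s-%d", g$transect_id, g$year)
  rownames(g) <- NULL
  g[, c("survey_id", "transect_id", "area_id", "year", "effort_km")]
}

#' Write transects as GeoJSON or vertex CSV
#'
#' @param transects a `transect_set`.
#' @param path output file; extension `.geojson`/`.json` selects GeoJSON
#'   (planar coordinates), anything else a vertex CSV
#'   (`transect_id, vertex, x, y, area_id`).
#' @return the path, invisibly.
#' @export
write_transects <- function(transects, path) {
  info <- transects$info
  if (grepl("\\.(geo)?json$", path, ignore.case = TRUE)) {
    feats <- lapply(seq_along(transects$lines), function(i) {
      v <- transects$lines[[i]]
      list(type = "Feature",
           properties = list(transect_id = info$transect_id[i],
                             area_id = info$area_id[i],
                             length_km = info$length_km[i]),
           geometry = list(type = "LineString",
                           coordinates = lapply(seq_len(nrow(v)),
                                                function(r) unname(v[r, ]))))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    rows <- do.call(rbind, lapply(seq_along(transects$lines), function(i) {
      v <- transects$lines[[i]]
      data.frame(transect_id = info$transect_id[i], vertex = seq_len(nrow(v)),
                 x = v[, 1], y = v[, 2], area_id = info$area_id[i])
    }))
    utils::write.csv(rows, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read transects from a vertex CSV
#'
#' @param path CSV written by [write_transects()] (CSV form).
#' @return a `transect_set`.
#' @export
read_transects <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  ids <- unique(d$transect_id)
  lines <- lapply(ids, function(id) {
    v <- d[d$transect_id == id, ]
    v <- v[order(v$vertex), ]
    cbind(x = v$x, y = v$y)
  })
  names(lines) <- ids
  info <- data.frame(
    transect_id = ids,
    area_id = d$area_id[match(ids, d$transect_id)],
    length_km = vapply(lines, polyline_length_km, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(info) <- NULL
  structure(list(lines = lines, info = info), class = "transect_set")
}
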