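#' Vegetation modelling classes
#'
#' The 16 modelling classes derived from the 25 generalized vegetation-map
#' codes, in the order used throughout the package. "Exposed alpine ridges" is
#' first and serves as the reference (intercept) level in the selection model.
#'
#' @format character vector of length 16.
#' @export
VEG_LEVELS <- c(
  "Exposed alpine ridges",
  "Lowland forest",
  "Bilberry-low fern birch forest",
  "Crowberry birch forest",
  "Lichen-rich birch forest",
  "Ombrotrophic bog and low-grown lawn vegetation",
  "Tall-grown lawn vegetation",
  "Wet mires, sedge swamps and reed beds",
  "Graminoid alpine ridge",
  "Heather-rich alpine ridge",
  "Lichen-rich heathland",
  "Heather- and grass-rich early snow patch communities",
  "Fresh heather and dwarf-shrub communities",
  "Herb-rich meadows",
  "Grass and dwarf willow snow-patch vegetation",
  "Bryophyte late snow patch vegetation")

#' Label for map cells outside usable habitat
#' @export
NON_HABITAT <- "Non-habitat"

# original code -> modelling class. Codes 1-5 are the pooled lowland
# (coniferous-dominated) forests; 6-8 the sub-alpine birch forests kept as
# original classes; 9-11 bogs and open swamp; 12-20 the alpine classes;
# 21-25 water / agriculture / built-up / unclassified, i.e. non-habitat.
veg_code_map <- local({
  m <- character(25)
  m[1:5] <- "Lowland forest"
  m[6] <- "Bilberry-low fern birch forest"
  m[7] <- "Crowberry birch forest"
  m[8] <- "Lichen-rich birch forest"
  m[9] <- "Ombrotrophic bog and low-grown lawn vegetation"
  m[10] <- "Tall-grown lawn vegetation"
  m[11] <- "Wet mires, sedge swamps and reed beds"
  m[12] <- "Exposed alpine ridges"
  m[13] <- "Graminoid alpine ridge"
  m[14] <- "Heather-rich alpine ridge"
  m[15] <- "Lichen-rich heathland"
  m[16] <- "Heather- and grass-rich early snow patch communities"
  m[17] <- "Fresh heather and dwarf-shrub communities"
  m[18] <- "Herb-rich meadows"
  m[19] <- "Grass and dwarf willow snow-patch vegetation"
  m[20] <- "Bryophyte late snow patch vegetation"
  m[21:25] <- "Non-habitat"
  m
})

#' Reclassify original vegetation codes to modelling classes
#'
#' Maps the 25 generalized vegetation-map codes onto the 16 modelling classes
#' plus [NON_HABITAT]: lowland forest codes 1--5 are pooled, the three birch
#' forest codes (6--8), three bog/swamp codes (9--11) and nine alpine codes
#' (12--20) keep their original classes, and the remaining codes (water,
#' agriculture, built-up, unclassified) become non-habitat.
#'
#' @param code integer vector of codes in 1..25.
#' @return character vector of class names.
#' @export
reclassify_vegetation <- function(code) {
  if (any(is.na(code)) || any(code != round(code)) ||
      any(code < 1) || any(code > 25)) {
    stop("vegetation codes must be integers in 1..25")
  }
  veg_code_map[code]
}

#' North and east exposure from aspect
#'
#' Aspect is circular (0 deg = north = 360 deg), so it enters the model as two
#' components: `r = aspect * 2 * pi / 360`, north exposure `N = cos(r)` and
#' east exposure `E = sin(r)`.
#'
#' @param aspect_deg aspect in degrees, 0..360.
#' @return data.frame with `n_aspect`, `e_aspect`.
#' @export
aspect_components <- function(aspect_deg) {
  if (any(!is.finite(aspect_deg)) || any(aspect_deg < 0 | aspect_deg > 360)) {
    stop("aspect_deg must be in [0, 360]")
  }
  r <- aspect_deg * 2 * pi / 360
  data.frame(n_aspect = cos(r), e_aspect = sin(r))
}

#' Five-level categorical aspect
#'
#' North (315--45 deg, wrapping), east (45--135), south (135--225), west
#' (225--315), and flat where slope does not exceed `flat_threshold` (aspect
#' is undefined on flat ground). Intervals are half-open `[lo, hi)`.
#'
#' @param aspect_deg aspect, degrees.
#' @param slope_deg slope, degrees.
#' @param flat_threshold slope at or below which a cell is "flat" (default 0,
#'   exact flatness; raise for noisy real-world elevation models).
#' @return factor with levels flat, north, east, south, west (flat first, the
#'   model's reference level).
#' @export
aspect_category <- function(aspect_deg, slope_deg, flat_threshold = 0) {
  stopifnot(length(aspect_deg) == length(slope_deg))
  a <- aspect_deg %% 360
  out <- rep("north", length(a))
  out[a >= 45 & a < 135] <- "east"
  out[a >= 135 & a < 225] <- "south"
  out[a >= 225 & a < 315] <- "west"
  out[slope_deg <= flat_threshold] <- "flat"
  factor(out, levels = c("flat", "north", "east", "south", "west"))
}

#' Deviation in altitude from the regional timberline
#'
#' Elevation minus the regional empirical timberline (RET) elevation at the
#' same location; positive above the timberline, 0 at it.
#'
#' @param elevation_m elevation, metres a.s.l.
#' @param ret_m RET elevation, metres a.s.l. (`NA` propagates).
#' @return deviation in metres.
#' @export
timberline_deviation <- function(elevation_m, ret_m) {
  elevation_m - ret_m
}

#' Extract model covariates at point locations
#'
#' Point-in-cell lookup on each raster (no interpolation); slope and aspect
#' come from the landscape's elevation-derived terrain rasters. Points outside
#' the raster extent raise an error with their coordinates.
#'
#' @param landscape a `ptarmigan_landscape`.
#' @param points data.frame with `x`, `y` (and any id columns, carried
#'   through).
#' @param flat_threshold passed to [aspect_category()].
#' @return data.frame: the input columns plus `veg_code`, `veg_class` (factor
#'   over [VEG_LEVELS] plus [NON_HABITAT]), `elevation_m`, `ret_m`,
#'   `timberline_dev_m`, `slope_deg`, `aspect_deg`, `n_aspect`, `e_aspect`,
#'   `aspect_cat`, `nonhabitat` (logical), `missing` (any raster `NA`).
#' @export
extract_covariates <- function(landscape, points, flat_threshold = 0) {
  idx <- cell_index(landscape, points$x, points$y)
  lin <- cbind(idx$row, idx$col)
  out <- points
  out$veg_code <- landscape$vegetation[lin]
  out$elevation_m <- landscape$elevation[lin]
  out$ret_m <- landscape$timberline[lin]
  out$timberline_dev_m <- timberline_deviation(out$elevation_m, out$ret_m)
  out$slope_deg <- landscape$slope_deg[lin]
  out$aspect_deg <- landscape$aspect_deg[lin]
  comp <- aspect_components(out$aspect_deg)
  out$n_aspect <- comp$n_aspect
  out$e_aspect <- comp$e_aspect
  out$aspect_cat <- aspect_category(out$aspect_deg, out$slope_deg,
                                    flat_threshold)
  cls <- reclassify_vegetation(out$veg_code)
  out$veg_class <- factor(cls, levels = c(VEG_LEVELS, NON_HABITAT))
  out$nonhabitat <- cls == NON_HABITAT
  out$missing <- is.na(out$veg_code) | is.na(out$elevation_m) |
    is.na(out$ret_m)
  out
}

#' Remove locations in non-habitat
#'
#' Used and available locations falling in non-habitat map classes are
#' excluded from the modelling set. The vegetation factor is narrowed to the
#' 16 modelling classes.
#'
#' @param records covariate records from [extract_covariates()] (used and/or
#'   available; a `used` column, if present, feeds the ledger row).
#' @param ledger optional ledger to append to.
#' @return list with `records` (kept rows) and `ledger`.
#' @export
drop_nonhabitat <- function(records, ledger = new_ledger()) {
  kept <- records[!records$nonhabitat & !records$missing, ]
  kept$veg_class <- factor(as.character(kept$veg_class), levels = VEG_LEVELS)
  if (!is.null(kept$used)) {
    ledger <- ledger_add(ledger, "Removed non-habitat (final dataset)",
                         used = sum(kept$used == 1),
                         available = sum(kept$used == 0))
  } else {
    ledger <- ledger_add(ledger, "Removed non-habitat (final dataset)",
                         used = nrow(kept))
  }
  list(records = kept, ledger = ledger)
}

#' Fit standardization parameters
#'
#' Centres and scales the continuous model terms to zero mean and unit
#' standard deviation (sample SD, n-1 denominator), computed on the combined
#' used + available modelling set. The parameters are stored with every model
#' fit so map predictions use the same scaling.
#'
#' @param records covariate records.
#' @param vars variables to standardize.
#' @return object of class `standardization_params`: named list of
#'   `c(mean, sd)` per variable.
#' @export
fit_standardization <- function(records,
                                vars = c("timberline_dev_m", "slope_deg",
                                         "n_aspect", "e_aspect")) {
  params <- lapply(vars, function(v) {
    x <- records[[v]]
    if (is.null(x)) stop("no column called ", v)
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) stop("zero standard deviation for ", v)
    c(mean = mean(x), sd = s)
  })
  names(params) <- vars
  structure(params, class = "standardization_params")
}

#' Apply (or invert) standardization
#'
#' Adds a `<var>_z` column per parameterised variable. Quadratic model terms
#' are squares of the standardized value and are formed at design-build time,
#' not here.
#'
#' @param records covariate records.
#' @param params a `standardization_params`.
#' @return records with `_z` columns appended.
#' @export
apply_standardization <- function(records, params) {
  for (v in names(params)) {
    records[[paste0(v, "_z")]] <- (records[[v]] - params[[v]]["mean"]) /
      params[[v]]["sd"]
  }
  records
}

#' @rdname apply_standardization
#' @export
invert_standardization <- function(records, params) {
  for (v in names(params)) {
    zc <- paste0(v, "_z")
    if (!is.null(records[[zc]])) {
      records[[v]] <- records[[zc]] * params[[v]]["sd"] + params[[v]]["mean"]
    }
  }
  records
}

#' Covariates for every cell of a landscape
#'
#' Convenience wrapper over [extract_covariates()] at all cell centres, used
#' for raster-wide prediction.
#'
#' @param landscape a `ptarmigan_landscape`.
#' @param flat_threshold passed to [aspect_category()].
#' @return covariate data.frame in row-major cell order.
#' @export
landscape_covariates <- function(landscape, flat_threshold = 0) {
  extract_covariates(landscape, cell_centres(landscape), flat_threshold)
}
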