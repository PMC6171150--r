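#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators do not perturb the global random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Smooth a matrix with a separable Gaussian kernel
#'
#' Edge cells are handled by replicate padding, so the output keeps the input
#' dimensions and has no edge attenuation. `sigma` is in cell units;
#' `sigma = 0` returns the input unchanged.
#'
#' @param mat numeric matrix.
#' @param sigma kernel standard deviation in cells.
#' @return smoothed matrix.
#' @keywords internal
gaussian_smooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  smooth_dim <- function(m, along_rows) {
    n <- if (along_rows) nrow(m) else ncol(m)
    out <- m * 0
    for (k in seq_along(w)) {
      o <- k - r - 1L
      idx <- pmin(pmax(seq_len(n) + o, 1L), n)  # clamp = replicate padding
      out <- out + w[k] * (if (along_rows) m[idx, , drop = FALSE]
                           else m[, idx, drop = FALSE])
    }
    out
  }
  smooth_dim(smooth_dim(mat, TRUE), FALSE)
}

# smoothed Gaussian random field, standardized to mean 0 / sd 1
random_field <- function(rows, cols, sigma) {
  z <- gaussian_smooth(matrix(stats::rnorm(rows * cols), rows, cols), sigma)
  (z - mean(z)) / stats::sd(as.vector(z))
}

#' Default vegetation mixing weights
#'
#' Expected areal share per original map code, proportional to the available-
#' location composition of the survey data (the "available sites" column of
#' the published category table), plus a small non-habitat share (about 1%,
#' the fraction of available locations the study removed as non-habitat). In
#' the 16-class mode a single representative code stands for the pooled
#' lowland-forest and non-habitat groups; in the 25-code mode the group weight
#' is split evenly across its codes, which exercises reclassification.
#'
#' @param codes `"generalized16"` (default) or `"full25"`.
#' @return named numeric vector of weights over vegetation codes, summing to 1.
#' @export
default_veg_weights <- function(codes = c("generalized16", "full25")) {
  codes <- match.arg(codes)
  avail <- c(`12` = 460, `6` = 1481, `11` = 633, `17` = 11380, `13` = 894,
             `18` = 994, `10` = 1767, `7` = 959, `8` = 929, `15` = 1063,
             `16` = 1924, `14` = 6955, `20` = 1100, `19` = 742, `9` = 3248)
  lowland <- 3620
  nonhab <- 385  # ~1% of the available total
  if (codes == "generalized16") {
    w <- c(avail, `3` = lowland, `23` = nonhab)
  } else {
    w <- c(avail,
           stats::setNames(rep(lowland / 5, 5), 1:5),
           stats::setNames(rep(nonhab / 5, 5), 21:25))
  }
  w <- w[order(as.integer(names(w)))]
  w / sum(w)
}

#' Balanced vegetation mixing weights
#'
#' Equal expected shares over the 16 modelling classes (one representative
#' code each) plus ~1% non-habitat. Used by the parameter-recovery experiment
#' so every selection contrast -- including those against the reference class
#' -- is informed by a comparable number of locations.
#'
#' @return named numeric vector of weights over vegetation codes, summing
#'   to 1.
#' @export
balanced_veg_weights <- function() {
  w <- c(stats::setNames(rep(0.99 / 16, 16), c(3, 6:20)), `23` = 0.01)
  w[order(as.integer(names(w)))]
}

#' Simulate a landscape raster stack
#'
#' Generates a spatially autocorrelated synthetic landscape emulating an
#' alpine survey region: a smooth elevation field, a smoothly varying regional
#' timberline, and a categorical vegetation raster whose classes form
#' contiguous patches with prescribed expected areal shares. Vegetation is
#' produced by thresholding a smoothed Gaussian field at the cumulative class
#' weights (probability-integral transform), which gives exact marginal shares
#' in expectation while preserving spatial autocorrelation. Deterministic
#' given `seed`.
#'
#' @param seed integer RNG seed.
#' @param rows,cols raster dimensions (both >= 16).
#' @param cell_size cell edge, metres (default 30, the vegetation-map
#'   resolution the selection model is built on).
#' @param veg_weights named numeric vector of expected shares per vegetation
#'   code; default [default_veg_weights()]. A single weight of 1 forces a
#'   constant vegetation raster.
#' @param veg_smoothness,elevation_smoothness,timberline_smoothness field
#'   correlation scales in cells.
#' @param elevation_base,elevation_relief mean and scale (m) of the elevation
#'   field; as `elevation_smoothness` grows the field flattens and derived
#'   slope tends to zero.
#' @param timberline_base,timberline_relief mean and scale (m) of the RET
#'   field.
#' @param codes vegetation coding mode passed to [default_veg_weights()] when
#'   `veg_weights` is `NULL`.
#' @return a [landscape_stack()] object.
#' @export
make_landscape <- function(seed, rows = 256, cols = 256, cell_size = 30,
                           veg_weights = NULL,
                           veg_smoothness = 6, elevation_smoothness = 25,
                           elevation_base = 900, elevation_relief = 120,
                           timberline_base = 900, timberline_relief = 60,
                           timberline_smoothness = 40,
                           codes = c("generalized16", "full25")) {
  if (rows < 16 || cols < 16) stop("rows and cols must both be >= 16")
  if (cell_size <= 0) stop("cell_size must be positive")
  codes <- match.arg(codes)
  if (is.null(veg_weights)) veg_weights <- default_veg_weights(codes)
  if (is.null(names(veg_weights)) ||
      any(!as.integer(names(veg_weights)) %in% 1:25)) {
    stop("veg_weights must be named by vegetation codes 1..25")
  }
  veg_weights <- veg_weights / sum(veg_weights)
  with_seed(seed, {
    elev <- elevation_base + elevation_relief *
      random_field(rows, cols, elevation_smoothness)
    ret <- timberline_base + timberline_relief *
      random_field(rows, cols, timberline_smoothness)
    if (length(veg_weights) == 1L) {
      veg <- matrix(as.integer(names(veg_weights)), rows, cols)
    } else {
      u <- stats::pnorm(random_field(rows, cols, veg_smoothness))
      br <- c(0, cumsum(veg_weights))
      br[length(br)] <- 1
      idx <- findInterval(u, br, rightmost.closed = TRUE, left.open = TRUE)
      idx <- pmin(pmax(idx, 1L), length(veg_weights))
      veg <- matrix(as.integer(names(veg_weights))[idx], rows, cols)
    }
    landscape_stack(veg, elev, ret, origin = c(0, 0), cellsize = cell_size)
  })
}
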