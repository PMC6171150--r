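#' Predict and bin the RSF across a landscape
#'
#' Evaluates the exponential RSF in every raster cell from the fitted
#' selection coefficients and the fit's stored standardization, scales the
#' values by the map maximum so they lie in (0, 1], and assigns each cell the
#' quantile-bin rank defined by the supplied cut points (the same bins used in
#' cross-validation, on the unscaled RSF scale). Non-habitat cells carry no
#' value.
#'
#' @param fit an `rsf_fit` from [fit_rsf()].
#' @param landscape a `ptarmigan_landscape` aligned with the covariates the
#'   model expects.
#' @param bin_edges interior cut points on the unscaled RSF scale; defaults to
#'   the 10-quantile edges of the map's own valid cells.
#' @param n_bins number of bins when `bin_edges` is computed here.
#' @param flat_threshold passed to covariate extraction.
#' @return object of class `binned_map`: list with `rsf` (scaled RSF matrix,
#'   max 1), `bin` (integer matrix 1..n_bins, `NA` outside habitat),
#'   `bin_edges`, `n_bins`, `landscape`.
#' @export
map_rsf <- function(fit, landscape, bin_edges = NULL, n_bins = 10,
                    flat_threshold = 0) {
  cov <- landscape_covariates(landscape, flat_threshold)
  w <- predict_rsf(fit, cov)
  if (is.null(bin_edges)) {
    bin_edges <- quantile_bin(w[is.finite(w)], n_bins)$edges
  }
  n_bins <- length(bin_edges) + 1L
  bins <- bin_values(w, bin_edges)
  # cell_centres() is row-major, so fill matrices by row
  to_mat <- function(v) matrix(v, landscape$nrow, landscape$ncol, byrow = TRUE)
  structure(list(rsf = to_mat(scale_rsf(w)), bin = to_mat(bins),
                 bin_edges = bin_edges, n_bins = n_bins,
                 landscape = landscape),
            class = "binned_map")
}

#' @export
print.binned_map <- function(x, ...) {
  valid <- sum(!is.na(x$bin))
  cat(sprintf("binned_map: %d x %d cells, %d bins, %.1f%% habitat\n",
              nrow(x$bin), ncol(x$bin), x$n_bins,
              100 * valid / length(x$bin)))
  invisible(x)
}

#' Cells within the surveyed line-buffers
#'
#' @param landscape a `ptarmigan_landscape`.
#' @param transects a `transect_set`.
#' @param half_width_m buffer half-width (m).
#' @return logical matrix on the landscape grid.
#' @export
buffer_mask <- function(landscape, transects, half_width_m = 200) {
  cc <- cell_centres(landscape)
  d <- rep(Inf, nrow(cc))
  for (line in transects$lines) {
    d <- pmin(d, dist_to_polyline(cbind(cc$x, cc$y), line))
  }
  matrix(d <= half_width_m, landscape$nrow, landscape$ncol, byrow = TRUE)
}

#' Per-bin percentage coverage of a binned map
#'
#' Three percentage columns per bin rank: share of all valid (habitat) map
#' cells, share of valid cells inside the surveyed buffers, and share of the
#' used locations. Each column sums to 100 up to rounding.
#'
#' @param binned_map a `binned_map`.
#' @param mask optional logical matrix (e.g. [buffer_mask()]) selecting the
#'   surveyed area.
#' @param used_points optional data.frame with `x`, `y` of used locations.
#' @return data.frame: `bin`, `domain_pct`, and when supplied `buffer_pct`,
#'   `used_pct`.
#' @export
summarize_bin_coverage <- function(binned_map, mask = NULL,
                                   used_points = NULL) {
  nb <- binned_map$n_bins
  pct <- function(bins) {
    bins <- bins[!is.na(bins)]
    if (!length(bins)) {
      warning("empty mask: coverage column is all zero")
      return(rep(0, nb))
    }
    100 * vapply(seq_len(nb), function(k) sum(bins == k), numeric(1)) /
      length(bins)
  }
  out <- data.frame(bin = seq_len(nb), domain_pct = pct(binned_map$bin))
  if (!is.null(mask)) out$buffer_pct <- pct(binned_map$bin[mask])
  if (!is.null(used_points)) {
    idx <- cell_index(binned_map$landscape, used_points$x, used_points$y)
    out$used_pct <- pct(binned_map$bin[cbind(idx$row, idx$col)])
  }
  out
}
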