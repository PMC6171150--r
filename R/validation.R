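#' Random k-fold partition of unit ids
#'
#' Random, seed-deterministic partition into `k` approximately equal folds
#' (sizes differ by at most 1).
#'
#' @param unit_ids vector of unit identifiers (>= k).
#' @param k number of folds.
#' @param seed integer seed.
#' @return data.frame `unit_id`, `fold` (1..k), of class `fold_plan`.
#' @export
kfold_split <- function(unit_ids, k = 5, seed = 1) {
  n <- length(unit_ids)
  if (k > n) stop("k exceeds the number of units")
  folds <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  structure(data.frame(unit_id = unit_ids, fold = folds),
            class = c("fold_plan", "data.frame"))
}

#' Stratified fold plan for modelling records
#'
#' Assigns folds separately within the used and the available records, so
#' every fold's used:available ratio stays close to the global ratio.
#'
#' @param records modelling records with a `used` column.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer fold label per record row.
#' @export
make_fold_plan <- function(records, k = 5, seed = 1) {
  fold <- integer(nrow(records))
  iu <- which(records$used == 1)
  ia <- which(records$used == 0)
  fold[iu] <- kfold_split(iu, k = min(k, length(iu)), seed = seed)$fold
  fold[ia] <- kfold_split(ia, k = min(k, length(ia)), seed = seed + 1)$fold
  fold
}

#' Spearman rank correlation between bin ranks and counts
#'
#' Average ranks for ties; the p-value uses the t approximation (the
#' conventional report for 10 bins), or the exact permutation distribution
#' when `exact = TRUE` and n is small.
#'
#' @param bin_rank bin ranks (1..n_bins).
#' @param counts used-location counts per bin.
#' @param exact use the exact null distribution (no ties only).
#' @return list with `rho` and `p_value`.
#' @export
spearman_rank_cor <- function(bin_rank, counts, exact = FALSE) {
  ct <- suppressWarnings(
    stats::cor.test(bin_rank, counts, method = "spearman", exact = exact))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

# one cross-validation evaluation: fit on train, bin test predictions,
# correlate bin rank with used counts
eval_split <- function(records, spec, train_idx, test_idx, n_bins,
                       binning_sample = c("all", "available")) {
  binning_sample <- match.arg(binning_sample)
  fit <- fit_rsf(records[train_idx, ], spec)
  test <- records[test_idx, ]
  w <- predict_rsf(fit, test)
  bs <- if (binning_sample == "all") w else w[test$used == 0]
  bins <- quantile_bin(bs[is.finite(bs)], n_bins)
  test_bin <- bin_values(w, bins$edges)
  counts <- vapply(seq_len(n_bins), function(b) {
    sum(test$used == 1 & test_bin == b, na.rm = TRUE)
  }, numeric(1))
  if (sum(counts) == 0) {
    warning("no used locations in the test set; rho undefined")
    return(list(rho = NA_real_, p_value = NA_real_, counts = counts))
  }
  sp <- spearman_rank_cor(seq_len(n_bins), counts)
  c(sp, list(counts = counts))
}

#' K-fold cross-validation with quantile-bin rank correlation
#'
#' For each fold: fit the model on the remaining folds, predict the withheld
#' test set, 10-quantile bin the test-set predictions (bin 1 = low relative
#' probability of selection, bin 10 = high), count used locations per bin,
#' and compute the Spearman rank correlation between bin rank and count. A
#' predictive model puts successively more used locations in higher bins
#' (strong positive rho).
#'
#' @param records modelling records.
#' @param spec `model_spec` fixed in advance.
#' @param fold_plan integer fold label per record (see [make_fold_plan()]).
#' @param n_bins number of quantile bins.
#' @param binning_sample `"all"` (used + available test points, default) or
#'   `"available"`.
#' @return object of class `validation_result`: data.frame `per_fold` (fold,
#'   rho, p_value), `mean_rho`, `bin_counts` (fold x bin).
#' @export
cv_boyce <- function(records, spec, fold_plan, n_bins = 10,
                     binning_sample = "all") {
  folds <- sort(unique(fold_plan))
  res <- lapply(folds, function(f) {
    tryCatch(
      eval_split(records, spec, which(fold_plan != f), which(fold_plan == f),
                 n_bins, binning_sample),
      error = function(e) {
        warning(sprintf("fold %s failed: %s", f, conditionMessage(e)))
        list(rho = NA_real_, p_value = NA_real_, counts = rep(NA_real_, n_bins))
      })
  })
  per_fold <- data.frame(
    fold = folds,
    rho = vapply(res, `[[`, numeric(1), "rho"),
    p_value = vapply(res, `[[`, numeric(1), "p_value"))
  counts <- do.call(rbind, lapply(res, `[[`, "counts"))
  dimnames(counts) <- list(paste0("fold", folds), paste0("bin", seq_len(n_bins)))
  structure(list(per_fold = per_fold,
                 mean_rho = mean(per_fold$rho, na.rm = TRUE),
                 bin_counts = counts),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  print(x$per_fold, row.names = FALSE)
  cat(sprintf("mean rho = %.3f\n", x$mean_rho))
  invisible(x)
}

#' Spatial-block cross-validation over geographical regions
#'
#' Leave-one-region-out application of the k-fold procedure: each region is
#' withheld in turn, the model is fitted to the remaining regions and
#' evaluated on the withheld one. Region labels are user input (the study's
#' regions were delimited by climatic similarity).
#'
#' @param records modelling records.
#' @param region_labels region label per record row (>= 2 regions).
#' @param spec `model_spec`.
#' @param n_bins number of quantile bins.
#' @param binning_sample see [cv_boyce()].
#' @return `validation_result` with one row per region.
#' @export
spatial_block_cv <- function(records, region_labels, spec, n_bins = 10,
                             binning_sample = "all") {
  regions <- sort(unique(region_labels))
  if (length(regions) < 2) stop("need >= 2 regions")
  res <- lapply(regions, function(rg) {
    tryCatch(
      eval_split(records, spec, which(region_labels != rg),
                 which(region_labels == rg), n_bins, binning_sample),
      error = function(e) {
        warning(sprintf("region %s failed: %s", rg, conditionMessage(e)))
        list(rho = NA_real_, p_value = NA_real_,
             counts = rep(NA_real_, n_bins))
      })
  })
  per_region <- data.frame(
    region = regions,
    rho = vapply(res, `[[`, numeric(1), "rho"),
    p_value = vapply(res, `[[`, numeric(1), "p_value"))
  counts <- do.call(rbind, lapply(res, `[[`, "counts"))
  dimnames(counts) <- list(regions, paste0("bin", seq_len(n_bins)))
  structure(list(per_fold = per_region,
                 mean_rho = mean(per_region$rho, na.rm = TRUE),
                 bin_counts = counts),
            class = "validation_result")
}

#' Area-adjusted validation against an independent point set
#'
#' Looks up the mapped RSF bin under each point, counts points per bin,
#' divides by the areal availability of the bin (its fraction of valid map
#' cells), and correlates bin rank with the adjusted counts. Points in empty
#' map cells (non-habitat or missing) are counted and excluded.
#'
#' @param points data.frame with `x`, `y`.
#' @param binned_map a `binned_map` from [map_rsf()].
#' @return list with `rho`, `p_value`, `table` (bin, count, area_fraction,
#'   adjusted), `n_excluded`.
#' @export
area_adjusted_validation <- function(points, binned_map) {
  idx <- cell_index(binned_map$landscape, points$x, points$y)
  b <- binned_map$bin[cbind(idx$row, idx$col)]
  n_excluded <- sum(is.na(b))
  b <- b[!is.na(b)]
  nb <- binned_map$n_bins
  count <- vapply(seq_len(nb), function(k) sum(b == k), numeric(1))
  valid <- !is.na(binned_map$bin)
  area_frac <- vapply(seq_len(nb), function(k) {
    sum(binned_map$bin[valid] == k)
  }, numeric(1)) / sum(valid)
  use <- area_frac > 0
  if (any(!use)) warning("bins with zero availability excluded: ",
                         paste(which(!use), collapse = ", "))
  adjusted <- ifelse(use, count / area_frac, NA_real_)
  sp <- spearman_rank_cor(seq_len(nb)[use], adjusted[use])
  list(rho = sp$rho, p_value = sp$p_value,
       table = data.frame(bin = seq_len(nb), count = count,
                          area_fraction = area_frac, adjusted = adjusted),
       n_excluded = n_excluded)
}
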