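test_that("k-fold partitions are balanced and seed-deterministic", {
  p1 <- kfold_split(1:100, k = 5, seed = 3)
  expect_equal(as.vector(table(p1$fold)), rep(20L, 5))
  p2 <- kfold_split(1:101, k = 5, seed = 3)
  expect_setequal(as.vector(table(p2$fold)), c(21L, 20L, 20L, 20L, 20L))
  expect_identical(p1$fold, kfold_split(1:100, k = 5, seed = 3)$fold)
  expect_false(identical(p1$fold, kfold_split(1:100, k = 5, seed = 4)$fold))
  expect_error(kfold_split(1:3, k = 5), "exceeds")
})

test_that("stratified fold plans preserve the used:available ratio", {
  rec <- data.frame(used = rep(c(1, 0), c(400, 1200)))
  fold <- make_fold_plan(rec, k = 5, seed = 2)
  ratios <- sapply(1:5, function(f) mean(rec$used[fold == f]))
  expect_true(all(abs(ratios - 0.25) < 0.025))
})

test_that("Spearman correlation matches a rank-then-Pearson oracle with
           average ranks for ties", {
  set.seed(71)
  for (i in 1:15) {
    n <- sample(5:20, 1)
    x <- sample(1:8, n, replace = TRUE)   # ties on purpose
    y <- sample(1:6, n, replace = TRUE)
    expect_equal(spearman_rank_cor(x, y)$rho, oracle_spearman(x, y),
                 tolerance = 1e-12)
  }
  expect_equal(spearman_rank_cor(1:10, c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10))$rho,
               1)
  expect_equal(spearman_rank_cor(1:10, 10:1)$rho, -1)
})

test_that("cross-validation recovers strong rank structure on the fitted
           pipeline data", {
  out <- small_pipeline()
  plan <- make_fold_plan(out$records, k = 5, seed = 8)
  cv <- cv_boyce(out$records, out$fit$spec, plan)
  expect_equal(nrow(cv$per_fold), 5)
  expect_true(all(is.finite(cv$per_fold$rho)))
  expect_true(all(cv$per_fold$rho >= -1 & cv$per_fold$rho <= 1))
  # counts per fold sum to the used locations of that fold
  used_per_fold <- sapply(sort(unique(plan)), function(f) {
    sum(out$records$used == 1 & plan == f)
  })
  expect_equal(unname(rowSums(cv$bin_counts)), unname(used_per_fold))
  expect_gt(cv$mean_rho, 0.5)  # strong simulated selection is detectable
})

test_that("spatial blocking is invariant to consistent region relabelling
           and degrades on an off-model region", {
  out <- small_pipeline()
  rec <- out$records
  regions <- ifelse(rec$area_id %in% c("A01", "A02"), "south", "north")
  a <- spatial_block_cv(rec, regions, out$fit$spec)
  relabel <- c(south = "S-block", north = "N-block")
  b <- spatial_block_cv(rec, unname(relabel[regions]), out$fit$spec)
  expect_equal(sort(a$per_fold$rho), sort(b$per_fold$rho))
  expect_error(spatial_block_cv(rec, rep("one", nrow(rec)), out$fit$spec),
               ">= 2 regions")
})

test_that("area-adjusted validation flags concentration in the top bin", {
  out <- small_pipeline()
  bm <- out$map
  # synthetic points all in bin-10 cells
  cc <- cell_centres(bm$landscape)
  top <- cc[which(as.vector(t(bm$bin)) == 10), ]
  pts <- top[sample(nrow(top), 200, replace = TRUE), c("x", "y")]
  res <- area_adjusted_validation(pts, bm)
  expect_true(all(res$table$count[1:9] == 0))
  expect_equal(res$table$count[10], 200)
  expect_gt(res$rho, 0)
})

test_that("area-adjusted counts are flat for uniform points and steep for
           RSF-proportional points", {
  out <- small_pipeline()
  bm <- out$map
  cc <- cell_centres(bm$landscape)
  valid <- !is.na(as.vector(t(bm$bin)))
  cells <- cc[valid, ]
  set.seed(72)
  # uniform over valid cells: rho near zero, mostly not significant
  p_vals <- replicate(50, {
    pts <- cells[sample(nrow(cells), 400, replace = TRUE), c("x", "y")]
    area_adjusted_validation(pts, bm)$p_value
  })
  expect_gte(sum(p_vals > 0.05), 43)
  # RSF-proportional sampling on a map with a controlled, moderate gradient:
  # adjusted counts grow with bin rank, giving near-perfect rank correlation
  ls2 <- make_landscape(73, rows = 40, cols = 40)
  bins <- matrix(rep(rep(1:10, each = 4), 40), 40, 40, byrow = TRUE)
  synth <- structure(
    list(rsf = bins / 10, bin = bins, bin_edges = (1:9 + 0.5) / 10,
         n_bins = 10, landscape = ls2),
    class = "binned_map")
  cc2 <- cell_centres(ls2)
  w2 <- as.vector(t(synth$rsf))
  pts <- cc2[sample(nrow(cc2), 3000, replace = TRUE, prob = w2), c("x", "y")]
  res <- area_adjusted_validation(pts, synth)
  expect_gte(res$rho, 0.9)
  expect_true(all(diff(tapply(res$table$adjusted, res$table$bin, mean)
                       [c(1, 5, 10)]) > 0))
})

test_that("bin coverage summaries conserve 100% per column", {
  out <- small_pipeline()
  cov <- out$coverage
  expect_equal(sum(cov$domain_pct), 100, tolerance = 1e-9)
  expect_equal(sum(cov$buffer_pct), 100, tolerance = 1e-9)
  expect_equal(sum(cov$used_pct), 100, tolerance = 1e-9)
  # degenerate cases on a hand-built map
  bm <- out$map
  used <- out$records[out$records$used == 1, c("x", "y")]
  idx <- cell_index(bm$landscape, used$x, used$y)
  all10 <- bm
  all10$bin[] <- ifelse(is.na(bm$bin), NA, 10L)
  cov10 <- summarize_bin_coverage(all10, used_points = used)
  expect_equal(cov10$used_pct, c(rep(0, 9), 100))
  expect_equal(cov10$domain_pct, c(rep(0, 9), 100))
})

test_that("the mapped RSF is consistent with point predictions and scaled to
           a maximum of one", {
  out <- small_pipeline()
  bm <- out$map
  expect_equal(max(bm$rsf, na.rm = TRUE), 1)
  cov <- landscape_covariates(bm$landscape,
                              out$config$flat_threshold_deg)
  w <- predict_rsf(out$fit, cov)
  expect_equal(as.vector(t(bm$rsf)), w / max(w, na.rm = TRUE),
               tolerance = 1e-12)
  # bins only on habitat cells
  expect_true(all(is.na(bm$bin[is.na(bm$rsf)])))
})
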