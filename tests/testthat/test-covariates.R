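test_that("aspect transforms to north/east exposure are exact", {
  expect_equal(aspect_components(0), data.frame(n_aspect = 1, e_aspect = 0))
  expect_equal(aspect_components(90)$e_aspect, 1)
  expect_equal(aspect_components(90)$n_aspect, 0, tolerance = 1e-12)
  expect_equal(aspect_components(180)$n_aspect, -1)
  comp <- aspect_components(runif(200, 0, 360))
  expect_equal(comp$n_aspect^2 + comp$e_aspect^2, rep(1, 200),
               tolerance = 1e-12)
  expect_error(aspect_components(400), "\\[0, 360\\]")
})

test_that("categorical aspect partitions the circle with wrap-around north", {
  expect_equal(as.character(aspect_category(10, 5)), "north")
  expect_equal(as.character(aspect_category(100, 5)), "east")
  expect_equal(as.character(aspect_category(200, 5)), "south")
  expect_equal(as.character(aspect_category(270, 5)), "west")
  expect_equal(as.character(aspect_category(350, 5)), "north")
  expect_equal(as.character(aspect_category(123, 0)), "flat")
  # half-open boundaries
  expect_equal(as.character(aspect_category(c(45, 135, 225, 315), rep(5, 4))),
               c("east", "south", "west", "north"))
  # complete and disjoint over the circle
  degs <- seq(0, 359.9, by = 0.1)
  cat <- aspect_category(degs, rep(5, length(degs)))
  expect_false(any(is.na(cat)))
  expect_setequal(unique(as.character(cat)),
                  c("north", "east", "south", "west"))
})

test_that("timberline deviation is elevation minus RET", {
  expect_equal(timberline_deviation(1000, 975), 25)
  expect_equal(timberline_deviation(800, 800), 0)
  expect_equal(timberline_deviation(600, 800), -200)
  expect_true(is.na(timberline_deviation(600, NA)))
})

test_that("reclassification maps 25 codes onto 16 classes plus non-habitat", {
  expect_equal(reclassify_vegetation(18), "Herb-rich meadows")
  expect_equal(reclassify_vegetation(3), "Lowland forest")
  expect_equal(reclassify_vegetation(12), "Exposed alpine ridges")
  all_classes <- reclassify_vegetation(1:25)
  habitat <- setdiff(unique(all_classes), NON_HABITAT)
  expect_equal(length(habitat), 16)
  expect_setequal(habitat, VEG_LEVELS)
  expect_equal(sum(all_classes == NON_HABITAT), 5)
  expect_error(reclassify_vegetation(0), "1..25")
  expect_error(reclassify_vegetation(26), "1..25")
})

test_that("non-habitat locations are dropped with a conserving ledger row", {
  rec <- data.frame(veg_code = c(rep(18, 8), 23, 25))
  rec$veg_class <- factor(reclassify_vegetation(rec$veg_code),
                          levels = c(VEG_LEVELS, NON_HABITAT))
  rec$nonhabitat <- rec$veg_class == NON_HABITAT
  rec$missing <- FALSE
  res <- drop_nonhabitat(rec)
  expect_equal(nrow(res$records), 8)
  expect_false(NON_HABITAT %in% levels(res$records$veg_class))
  clean <- drop_nonhabitat(rec[1:8, ])
  expect_equal(nrow(clean$records), 8)
})

test_that("standardization uses sample SD, round-trips, and rejects zero SD", {
  rec <- data.frame(timberline_dev_m = c(-1, 0, 1),
                    slope_deg = c(2, 4, 9),
                    n_aspect = c(0.2, -0.1, 0.4),
                    e_aspect = c(0.5, 0.1, -0.2))
  p <- fit_standardization(rec)
  z <- apply_standardization(rec, p)
  # sample SD of {-1,0,1} is 1, so values are unchanged
  expect_equal(z$timberline_dev_m_z, c(-1, 0, 1))
  expect_equal(mean(z$slope_deg_z), 0, tolerance = 1e-12)
  expect_equal(sd(z$slope_deg_z), 1, tolerance = 1e-12)
  back <- invert_standardization(z[, grepl("_z$", names(z)), drop = FALSE], p)
  expect_equal(back$timberline_dev_m, rec$timberline_dev_m,
               tolerance = 1e-12)
  expect_equal(back$slope_deg, rec$slope_deg, tolerance = 1e-12)
  bad <- rec; bad$slope_deg <- 5
  expect_error(fit_standardization(bad), "slope_deg")
})

test_that("covariate extraction is the cell-containing lookup", {
  ls1 <- make_landscape(21, rows = 20, cols = 20, cell_size = 30)
  cc <- cell_centres(ls1)
  i <- c(1, 57, 400)
  cov <- extract_covariates(ls1, cc[i, c("x", "y")])
  expect_equal(cov$veg_code, ls1$vegetation[cbind(cc$row[i], cc$col[i])])
  expect_equal(cov$elevation_m, ls1$elevation[cbind(cc$row[i], cc$col[i])])
  expect_equal(cov$timberline_dev_m, cov$elevation_m - cov$ret_m)
})

test_that("a flat landscape yields slope zero and flat aspect everywhere", {
  ls1 <- make_landscape(22, rows = 16, cols = 16, elevation_relief = 0)
  cov <- landscape_covariates(ls1)
  expect_true(all(cov$slope_deg == 0))
  expect_true(all(cov$aspect_cat == "flat"))
})
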