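test_that("available-location counts follow the effort-times-3 rule", {
  # 4-km transect surveyed in 4 years: 16 km of effort
  expect_identical(n_available(16), 48L)
  expect_identical(n_available(1), 3L)
  # fractional effort rounds to nearest, ties away from zero
  expect_identical(n_available(2.5), 8L)
  expect_identical(n_available(0), 0L)
  expect_error(n_available(-1), "non-negative")
})

test_that("buffer sampling is uniform over the strip", {
  line <- flat_line(0, 2000)
  expect_equal(nrow(sample_in_buffer(0, line)), 0)
  set.seed(41)
  pts <- sample_in_buffer(3000, line, half_width_m = 200)
  d <- dist_to_polyline(cbind(pts$x, pts$y), line)
  expect_true(all(d <= 200 + 1e-9))
  expect_equal(pts$perp_distance_m, d, tolerance = 1e-9)
  # perpendicular distances uniform on [0, 200]
  ks <- suppressWarnings(ks.test(pts$perp_distance_m, "punif", 0, 200))
  expect_gt(ks$p.value, 0.01)
  # positions uniform along the line as well
  ks2 <- suppressWarnings(ks.test(pts$x, "punif", 0, 2000))
  expect_gt(ks2$p.value, 0.01)
})

test_that("half-normal MLE equals the closed form and scales with distance", {
  fit <- fit_halfnormal(rep(50, 20))
  expect_equal(fit$sigma_m, 50, tolerance = 1e-10)
  expect_equal(fit_halfnormal(c(30, 40))$sigma_m, sqrt((900 + 1600) / 2),
               tolerance = 1e-10)
  set.seed(42)
  d <- abs(rnorm(400, 0, 70))
  expect_equal(fit_halfnormal(d)$sigma_m, sqrt(mean(d^2)), tolerance = 1e-10)
  expect_equal(fit_halfnormal(3 * d)$sigma_m, 3 * fit_halfnormal(d)$sigma_m,
               tolerance = 1e-8)
  expect_error(fit_halfnormal(c(0, 0, 0)), "degenerate")
})

test_that("truncated likelihood fit approaches the closed form when the
           truncation is far beyond sigma", {
  set.seed(43)
  d <- abs(rnorm(500, 0, 50))
  d <- d[d <= 200]
  untrunc <- fit_halfnormal(d)$sigma_m
  trunc <- fit_halfnormal(d, truncation = 200)$sigma_m
  expect_equal(trunc, untrunc, tolerance = 0.01)
  expect_gt(trunc, untrunc)  # truncation correction inflates sigma slightly
})

test_that("detection probability is exp(-d^2/(2 sigma^2))", {
  expect_equal(detection_probability(0, 60), 1)
  expect_equal(detection_probability(60, 60), exp(-0.5))
  expect_equal(detection_probability(120, 60), exp(-2))
  expect_error(detection_probability(-5, 60), "non-negative")
  d <- seq(0, 300, by = 10)
  expect_true(all(diff(detection_probability(d, 60)) < 0))
})

test_that("rejection thinning keeps points iff P < O and matches the
           truncated half-normal in distribution", {
  pts <- data.frame(perp_distance_m = runif(500, 0, 200))
  set.seed(44)
  th <- thin_by_detection(pts, 60)
  expect_identical(th$kept, th$p_i < th$o_i)
  # sigma large: essentially everything kept; sigma tiny: nothing
  expect_true(all(thin_by_detection(pts, 1e9)$kept))
  expect_false(any(thin_by_detection(pts, 1e-6)$kept))

  set.seed(45)
  big <- thin_by_detection(data.frame(perp_distance_m = runif(6000, 0, 200)),
                           60)
  kept <- big$perp_distance_m[big$kept]
  # truncated half-normal CDF on [0, 200]
  cdf <- function(q) (pnorm(q / 60) - 0.5) / (pnorm(200 / 60) - 0.5)
  ks <- suppressWarnings(ks.test(kept, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("per-survey substreams: adding a survey leaves others untouched", {
  setup <- single_transect_setup(n_surveys = 3)
  d_used <- abs(rnorm(50, 0, 60))
  a2 <- generate_availability(setup$transects, setup$surveys[1:2, ],
                              used_distances = d_used, seed = 9)
  a3 <- generate_availability(setup$transects, setup$surveys,
                              used_distances = d_used, seed = 9)
  two <- a3$points[a3$points$survey_id %in% setup$surveys$survey_id[1:2], ]
  expect_equal(two$x, a2$points$x)
  expect_equal(two$p_i, a2$points$p_i)
  # ledger records generation then thinning, with non-increasing counts
  expect_equal(a3$ledger$action[1:2],
               c("Generated random locations", "Adjusted random locations"))
  expect_lte(a3$ledger$available[2], a3$ledger$available[1])
})

test_that("detection fit serializes to a readable key-value file", {
  fit <- fit_halfnormal(c(30, 40, 55), truncation = 200)
  p <- tempfile()
  write_detection(fit, p)
  txt <- readLines(p)
  expect_match(txt[1], "^sigma_m ")
  expect_match(txt[4], "truncation 200")
})
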