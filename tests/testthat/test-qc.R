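test_that("perpendicular distance handles interior points and endpoint capping", {
  line <- flat_line(0, 1000)
  expect_equal(perpendicular_distance(c(0, 100), line), 100)
  expect_equal(perpendicular_distance(c(500, 0), line), 0)
  # beyond the end vertex: distance to the endpoint, not the infinite line
  expect_equal(perpendicular_distance(c(1100, 50), line),
               sqrt(100^2 + 50^2), tolerance = 1e-9)
  expect_error(perpendicular_distance(c(0, 0), cbind(1, 1)), "2 vertices")
  expect_error(perpendicular_distance(c(0, 0), rbind(c(1, 1), c(1, 1))),
               "degenerate")
})

test_that("distance to bending polylines matches a dense brute-force oracle", {
  set.seed(31)
  for (case in 1:12) {
    polyline <- cbind(x = cumsum(runif(4, -8, 8)),
                      y = cumsum(runif(4, -8, 8)))
    pt <- c(runif(1, -10, 10), runif(1, -10, 10))
    expect_equal(perpendicular_distance(pt, polyline),
                 oracle_polyline_distance(pt, polyline),
                 tolerance = 1e-3)
  }
})

test_that("the line-buffer boundary is inclusive", {
  line <- flat_line()
  expect_true(in_buffer(line, c(500, 150)))
  expect_false(in_buffer(line, c(500, 250)))
  expect_true(in_buffer(line, c(500, 200)))
  expect_error(in_buffer(line, c(0, 0), half_width_m = 0), "positive")
})

test_that("QC removes outside-buffer then >30-m deviation observations", {
  setup <- single_transect_setup()
  dist <- c(50, 150, 210, 90, 100)
  devn <- c(0, 0, 0, 40, 10)
  obs <- data.frame(survey_id = "T001-2014", x = seq(100, 500, by = 100),
                    y = dist, reported_perp_distance_m = dist + devn)
  res <- apply_qc(obs, setup$transects, setup$surveys)
  expect_equal(sum(res$observations$qc_status == "retained"), 3)
  expect_equal(sum(res$observations$qc_status == "removed_buffer"), 1)
  expect_equal(sum(res$observations$qc_status == "removed_deviation"), 1)
  expect_equal(res$observations$qc_status[3], "removed_buffer")
  expect_equal(res$observations$qc_status[4], "removed_deviation")
  # ledger: 5 -> 4 -> 3, conservation at every step
  expect_equal(res$ledger$used, c(5L, 4L, 3L))
})

test_that("boundary cases: 200 m stays, exactly 30-m deviation stays", {
  setup <- single_transect_setup()
  obs <- data.frame(survey_id = "T001-2014", x = c(100, 200),
                    y = c(200, 100),
                    reported_perp_distance_m = c(200, 130))
  res <- apply_qc(obs, setup$transects, setup$surveys)
  expect_equal(res$observations$qc_status, c("retained", "retained"))
})

test_that("QC is the identity on clean data and idempotent in general", {
  setup <- single_transect_setup()
  set.seed(7)
  obs <- data.frame(survey_id = "T001-2014", x = runif(40, 0, 1000),
                    y = runif(40, -250, 250))
  obs$reported_perp_distance_m <- abs(obs$y) + rnorm(40, 0, 25)
  res1 <- apply_qc(obs, setup$transects, setup$surveys)
  res2 <- apply_qc(res1$retained[, names(obs)], setup$transects,
                   setup$surveys)
  expect_equal(nrow(res2$retained), nrow(res1$retained))
  expect_true(all(res2$observations$qc_status == "retained"))

  clean <- data.frame(survey_id = "T001-2014", x = runif(10, 0, 1000),
                      y = runif(10, -150, 150))
  clean$reported_perp_distance_m <- abs(clean$y)
  resc <- apply_qc(clean, setup$transects, setup$surveys)
  expect_equal(nrow(resc$retained), 10)
})

test_that("orphan observations are rejected with their survey ids", {
  setup <- single_transect_setup()
  obs <- data.frame(survey_id = c("T001-2014", "GHOST-1"), x = c(1, 2),
                    y = c(1, 2), reported_perp_distance_m = c(1, 2))
  expect_error(apply_qc(obs, setup$transects, setup$surveys), "GHOST-1")
})

test_that("empty surveys leave the used side but stay for availability", {
  setup <- single_transect_setup(n_surveys = 3)
  obs <- data.frame(survey_id = c("T001-2014", "T001-2015"), x = c(100, 200),
                    y = c(50, 60),
                    reported_perp_distance_m = c(50, 60))
  qc <- apply_qc(obs, setup$transects, setup$surveys)
  res <- drop_empty_surveys(qc$retained, setup$surveys, ledger = qc$ledger)
  expect_equal(nrow(res$surveys_used), 2)
  expect_equal(nrow(res$surveys_all), 3)
  # availability generation still covers all three surveys
  av <- generate_availability(setup$transects, res$surveys_all,
                              used_distances = c(50, 60), seed = 1)
  expect_setequal(unique(av$points$survey_id), setup$surveys$survey_id)
  # all-empty case warns
  expect_warning(drop_empty_surveys(qc$retained[0, ], setup$surveys),
                 "empty")
})
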