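# shared fixtures, built once per test run and cached

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# a small but complete pipeline run: balanced composition so every vegetation
# class is informed, single candidate model to keep it quick
small_pipeline <- function() {
  cached("small_pipeline", {
    cfg <- pipeline_config(seed = 11, rows = 140, cols = 140, n_areas = 4,
                           used_per_km = 3,
                           veg_weights = balanced_veg_weights(),
                           candidates = list(model_spec()))
    suppressWarnings(run_pipeline(cfg))
  })
}

# straight east-west test transect on y = 0
flat_line <- function(x1 = 0, x2 = 1000) cbind(x = c(x1, x2), y = c(0, 0))

# one-transect survey scaffolding for QC tests
single_transect_setup <- function(length_m = 1000, n_surveys = 1) {
  lines <- list(T001 = flat_line(0, length_m))
  info <- data.frame(transect_id = "T001", area_id = "A01",
                     length_km = length_m / 1000)
  tr <- structure(list(lines = lines, info = info), class = "transect_set")
  surveys <- data.frame(
    survey_id = sprintf("T001-%d", seq_len(n_surveys) + 2013),
    transect_id = "T001", area_id = "A01",
    year = seq_len(n_surveys) + 2013, effort_km = length_m / 1000)
  list(transects = tr, surveys = surveys)
}

# synthetic modelling records with all 16 vegetation classes represented
toy_records <- function(n = 800, seed = 5) {
  withr_seed <- function(expr) {
    set.seed(seed); on.exit(set.seed(NULL)); expr
  }
  withr_seed({
    veg <- factor(sample(VEG_LEVELS, n, replace = TRUE), levels = VEG_LEVELS)
    # guarantee every level occurs
    veg[seq_along(VEG_LEVELS)] <- VEG_LEVELS
    aspect <- stats::runif(n, 0, 360)
    slope <- stats::rexp(n, 1 / 6)
    comp <- aspect_components(aspect)
    data.frame(
      used = stats::rbinom(n, 1, 0.4),
      area_id = sample(sprintf("A%02d", 1:6), n, replace = TRUE),
      veg_class = veg,
      timberline_dev_m = stats::rnorm(n, 0, 100),
      slope_deg = slope,
      aspect_deg = aspect,
      n_aspect = comp$n_aspect,
      e_aspect = comp$e_aspect,
      aspect_cat = aspect_category(aspect, slope, flat_threshold = 1))
  })
}

# brute-force point-to-polyline distance: dense discretization of every
# segment (independent of the analytic projection code)
oracle_polyline_distance <- function(point, polyline, step = 0.005) {
  best <- Inf
  for (s in seq_len(nrow(polyline) - 1)) {
    a <- polyline[s, ]; b <- polyline[s + 1, ]
    len <- sqrt(sum((b - a)^2))
    t <- seq(0, 1, length.out = max(2, ceiling(len / step)))
    px <- a[1] + t * (b[1] - a[1]); py <- a[2] + t * (b[2] - a[2])
    best <- min(best, sqrt((point[1] - px)^2 + (point[2] - py)^2))
  }
  best
}

# rank-then-Pearson Spearman oracle with hand-rolled average ranks
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    o <- order(v)
    r <- numeric(length(v))
    i <- 1
    while (i <= length(v)) {
      j <- i
      while (j < length(v) && v[o[j + 1]] == v[o[i]]) j <- j + 1
      r[o[i:j]] <- mean(i:j)
      i <- j + 1
    }
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# marginal log-likelihood of a random-intercept logistic model by adaptive
# quadrature (base integrate), independent of the fitting code
oracle_marginal_loglik <- function(y, X, groups, beta, var_g) {
  eta0 <- as.vector(X %*% beta)
  total <- 0
  for (g in unique(groups)) {
    i <- groups == g
    f <- function(b) {
      vapply(b, function(bb) {
        eta <- eta0[i] + bb
        sum(stats::dbinom(y[i], 1, stats::plogis(eta), log = TRUE)) +
          stats::dnorm(bb, 0, sqrt(var_g), log = TRUE)
      }, numeric(1))
    }
    # centre the integrand to avoid underflow
    m <- stats::optimize(f, c(-10, 10), maximum = TRUE)$objective
    val <- stats::integrate(function(b) exp(f(b) - m), -Inf, Inf,
                            rel.tol = 1e-10)$value
    total <- total + m + log(val)
  }
  total
}
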