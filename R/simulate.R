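#' Ground truth for a simulated selection study
#'
#' Bundles the true selection coefficients, between-area density
#' heterogeneity, and detection scale used to generate surveys, so the
#' recovery of every parameter can be checked against it. Coefficients are on
#' the raw covariate scale (per metre of timberline deviation, per degree of
#' slope); the defaults echo the published selection-strength estimates for
#' late-summer willow ptarmigan, converted from the standardized scale with
#' assumed dispersions of 100 m (timberline deviation) and 5 degrees (slope).
#'
#' @param beta_veg named numeric vector of log relative selection strengths
#'   per vegetation class relative to "Exposed alpine ridges" (missing classes
#'   default to 0).
#' @param beta_timberline length-2 `c(linear, quadratic)` on metres.
#' @param beta_slope length-2 `c(linear, quadratic)` on degrees.
#' @param beta_aspect length-2 `c(north, east)` on the cos/sin exposure
#'   components (default no aspect effect, the structure of the selected
#'   published model).
#' @param area_sd standard deviation of per-area log-density intercepts
#'   (>= 0).
#' @param sigma_detect half-normal detection scale, metres (> 0; `Inf` for no
#'   detection decay).
#' @return object of class `truth_record`.
#' @export
truth_record <- function(beta_veg = default_truth_beta_veg(),
                         beta_timberline = c(0.071 / 100, -0.257 / 100^2),
                         beta_slope = c(0.159 / 5, -0.193 / 5^2),
                         beta_aspect = c(0, 0),
                         area_sd = 0.5, sigma_detect = 60) {
  if (sigma_detect <= 0) stop("sigma_detect must be positive")
  if (area_sd < 0) stop("area_sd must be non-negative")
  bv <- stats::setNames(rep(0, length(VEG_LEVELS)), VEG_LEVELS)
  if (length(beta_veg)) {
    unknown <- setdiff(names(beta_veg), VEG_LEVELS)
    if (length(unknown)) stop("unknown vegetation class: ",
                              paste(unknown, collapse = ", "))
    bv[names(beta_veg)] <- beta_veg
  }
  if (bv[["Exposed alpine ridges"]] != 0) {
    stop("the reference class 'Exposed alpine ridges' must have beta 0")
  }
  structure(list(beta_veg = bv,
                 beta_timberline = as.numeric(beta_timberline),
                 beta_slope = as.numeric(beta_slope),
                 beta_aspect = as.numeric(beta_aspect),
                 area_sd = area_sd, sigma_detect = sigma_detect),
            class = "truth_record")
}

#' Default vegetation selection strengths
#'
#' Log relative selection strengths per class (reference Exposed alpine
#' ridges), matching the published point estimates for the most parsimonious
#' late-summer model.
#'
#' @return named numeric vector over the 15 non-reference classes.
#' @export
default_truth_beta_veg <- function() {
  c("Bilberry-low fern birch forest" = 0.480,
    "Wet mires, sedge swamps and reed beds" = 0.493,
    "Fresh heather and dwarf-shrub communities" = 0.825,
    "Graminoid alpine ridge" = 0.460,
    "Herb-rich meadows" = 1.126,
    "Tall-grown lawn vegetation" = 0.830,
    "Crowberry birch forest" = 0.731,
    "Lichen-rich birch forest" = 0.346,
    "Lichen-rich heathland" = -0.233,
    "Heather- and grass-rich early snow patch communities" = 0.492,
    "Heather-rich alpine ridge" = 0.599,
    "Lowland forest" = 0.355,
    "Bryophyte late snow patch vegetation" = 0.273,
    "Grass and dwarf willow snow-patch vegetation" = 0.026,
    "Ombrotrophic bog and low-grown lawn vegetation" = 0.928)
}

#' True log selection strength at covariate records
#'
#' Raw-scale linear predictor `beta' x` of a truth record; non-habitat or
#' missing records get `-Inf` (never used).
#'
#' @param truth a `truth_record`.
#' @param records covariate records from [extract_covariates()].
#' @return numeric vector.
#' @export
true_linear_predictor <- function(truth, records) {
  lp <- rep(-Inf, nrow(records))
  ok <- !records$nonhabitat & !records$missing
  cls <- as.character(records$veg_class[ok])
  td <- records$timberline_dev_m[ok]
  sl <- records$slope_deg[ok]
  lp[ok] <- truth$beta_veg[cls] +
    truth$beta_timberline[1] * td + truth$beta_timberline[2] * td^2 +
    truth$beta_slope[1] * sl + truth$beta_slope[2] * sl^2 +
    truth$beta_aspect[1] * records$n_aspect[ok] +
    truth$beta_aspect[2] * records$e_aspect[ok]
  lp
}

#' Express a raw-scale truth on a fit's standardized scale
#'
#' The fitted model is a deterministic linear reparameterization of the
#' raw-scale truth: with `z = (x - m) / s`, a raw contribution
#' `t1 x + t2 x^2` equals `const + s (t1 + 2 t2 m) z + t2 s^2 z^2`. This maps
#' the truth exactly onto the fitted coefficient names so bias and coverage
#' can be assessed term by term.
#'
#' @param truth a `truth_record`.
#' @param std_params the fit's `standardization_params`.
#' @param spec the fitted `model_spec`.
#' @return named numeric vector over the fixed-effect design columns
#'   (intercept `NA`: it absorbs sampling ratios and is not a selection
#'   parameter).
#' @export
truth_on_standardized_scale <- function(truth, std_params,
                                        spec = model_spec()) {
  out <- c("(Intercept)" = NA_real_)
  for (lev in VEG_LEVELS[-1]) {
    out[paste0("veg_class", lev)] <- truth$beta_veg[[lev]]
  }
  quad_map <- function(t, p) {
    m <- p[["mean"]]; s <- p[["sd"]]
    c(linear = s * (t[1] + 2 * t[2] * m), quadratic = t[2] * s^2)
  }
  if (spec$timberline != "none") {
    q <- quad_map(truth$beta_timberline, std_params$timberline_dev_m)
    out["timberline_dev_m_z"] <- q["linear"]
    if (spec$timberline == "quadratic") {
      out["I(timberline_dev_m_z^2)"] <- q["quadratic"]
    }
  }
  if (spec$slope != "none") {
    q <- quad_map(truth$beta_slope, std_params$slope_deg)
    out["slope_deg_z"] <- q["linear"]
    if (spec$slope == "quadratic") out["I(slope_deg_z^2)"] <- q["quadratic"]
  }
  if (spec$aspect == "ns" || spec$aspect == "ns_ew") {
    out["n_aspect_z"] <- truth$beta_aspect[1] * std_params$n_aspect[["sd"]]
  }
  if (spec$aspect == "ns_ew") {
    out["e_aspect_z"] <- truth$beta_aspect[2] * std_params$e_aspect[["sd"]]
  }
  out
}

# cells of `landscape` whose centre lies within `width` of any line of the
# area's transects; returns covariate records
area_buffer_cells <- function(landscape, transects, area_id, width) {
  cc <- cell_centres(landscape)
  ids <- transects$info$transect_id[transects$info$area_id == area_id]
  d <- rep(Inf, nrow(cc))
  for (tid in ids) {
    d <- pmin(d, dist_to_polyline(cbind(cc$x, cc$y), transects$lines[[tid]]))
  }
  cc[d <= width, , drop = FALSE]
}

#' Simulate line-transect surveys of a selecting population
#'
#' Generates willow-ptarmigan-like observations with the statistical structure
#' the selection analysis assumes: candidate locations fall uniformly in the
#' transect buffers, are retained with probability proportional to
#' `exp(beta' x)` (habitat selection, intensity normalized per survey area so
#' expected counts are controllable) times `exp(-d^2 / (2 sigma^2))`
#' (half-normal detection decay with perpendicular line distance), and carry a
#' per-area log-density intercept drawn from `N(0, area_sd^2)`. Reported
#' distances get optional Gaussian error (folded at zero) to exercise the
#' deviation QC filter; true distances are kept for oracle tests.
#'
#' @param landscape a `ptarmigan_landscape`.
#' @param transects a `transect_set` whose buffers lie inside the landscape.
#' @param truth a `truth_record`.
#' @param seed integer seed (deterministic output).
#' @param years survey years (one survey per transect per year).
#' @param used_per_km expected recorded observations per km of effort in an
#'   average-density area.
#' @param gen_half_width_m half-width of the candidate strip (m); slightly
#'   wider than the QC buffer so the buffer filter sees some out-of-buffer
#'   observations, as real data do.
#' @param distance_error_sd SD of reported-distance error (m); 0 for exact
#'   reporting.
#' @return list with `observations` (recorded detections: `survey_id`,
#'   `transect_id`, `area_id`, `year`, `x`, `y`, `reported_perp_distance_m`,
#'   `true_perp_distance_m`), `surveys` (the survey table), and
#'   `area_intercepts` (the intercepts actually drawn).
#' @export
simulate_survey <- function(landscape, transects, truth, seed,
                            years = 2014:2017, used_per_km = 0.55,
                            gen_half_width_m = 240, distance_error_sd = 20) {
  surveys <- survey_table(transects, years)
  areas <- sort(unique(surveys$area_id))
  with_seed(seed, {
    b_area <- stats::setNames(stats::rnorm(length(areas), 0, truth$area_sd),
                              areas)
    # per-area normalization: mean acceptance over the buffer, so the
    # candidate rate yields the requested recorded rate
    max_lp <- rate_cand <- stats::setNames(numeric(length(areas)), areas)
    W <- gen_half_width_m
    mean_g <- if (is.infinite(truth$sigma_detect)) 1 else {
      s <- truth$sigma_detect
      s * sqrt(2 * pi) * (stats::pnorm(W / s) - 0.5) / W
    }
    for (a in areas) {
      cells <- area_buffer_cells(landscape, transects, a,
                                 W + landscape$cellsize)
      cov <- extract_covariates(landscape, cells)
      lp <- true_linear_predictor(truth, cov)
      if (!any(is.finite(lp))) {
        stop("no habitat cells in the buffers of survey area ", a)
      }
      max_lp[a] <- max(lp[is.finite(lp)])
      mean_w <- mean(exp(pmax(lp - max_lp[a], -745)))
      rate_cand[a] <- used_per_km / (mean_w * mean_g)
    }
    obs <- vector("list", nrow(surveys))
    for (i in seq_len(nrow(surveys))) {
      sv <- surveys[i, ]
      a <- sv$area_id
      n_cand <- stats::rpois(1, rate_cand[a] * exp(b_area[a]) * sv$effort_km)
      if (n_cand == 0) next
      pts <- sample_in_buffer(n_cand, transects$lines[[sv$transect_id]], W)
      cov <- extract_covariates(landscape, pts)
      lp <- true_linear_predictor(truth, cov)
      p <- exp(pmin(lp - max_lp[a], 0)) *
        detection_probability(pts$perp_distance_m, truth$sigma_detect)
      keep <- stats::runif(n_cand) < p
      if (!any(keep)) next
      k <- pts[keep, , drop = FALSE]
      err <- if (distance_error_sd > 0) {
        stats::rnorm(nrow(k), 0, distance_error_sd)
      } else 0
      obs[[i]] <- data.frame(
        survey_id = sv$survey_id, transect_id = sv$transect_id,
        area_id = a, year = sv$year, x = k$x, y = k$y,
        reported_perp_distance_m = abs(k$perp_distance_m + err),
        true_perp_distance_m = k$perp_distance_m)
    }
    obs <- obs[!vapply(obs, is.null, logical(1))]
    observations <- if (length(obs)) do.call(rbind, obs) else
      data.frame(survey_id = character(), transect_id = character(),
                 area_id = character(), year = integer(), x = numeric(),
                 y = numeric(), reported_perp_distance_m = numeric(),
                 true_perp_distance_m = numeric())
    rownames(observations) <- NULL
    list(observations = observations, surveys = surveys,
         area_intercepts = b_area)
  })
}

#' Run QC, availability, covariate extraction and assembly for one simulation
#'
#' Convenience chain used by the recovery experiment and the pipeline: applies
#' the buffer and deviation filters, drops empty surveys, generates
#' detection-adjusted available locations over all surveys, extracts and
#' cleans covariates, and returns the modelling records (used = 1 /
#' available = 0) plus the accounting ledger.
#'
#' @param landscape,transects the simulated landscape and transects.
#' @param observations,surveys output of [simulate_survey()].
#' @param seed seed for the availability substreams.
#' @param buffer_m,max_deviation_m QC settings.
#' @param multiplier available locations per km of effort.
#' @param flat_threshold passed to [extract_covariates()].
#' @return list with `records`, `detection`, `ledger`, `qc`.
#' @export
assemble_modelling_data <- function(landscape, transects, observations,
                                    surveys, seed, buffer_m = 200,
                                    max_deviation_m = 30, multiplier = 3,
                                    flat_threshold = 0) {
  qc <- apply_qc(observations, transects, surveys, buffer_m = buffer_m,
                 max_deviation_m = max_deviation_m)
  emp <- drop_empty_surveys(qc$retained, surveys, ledger = qc$ledger)
  av <- generate_availability(
    transects, emp$surveys_all,
    used_distances = qc$retained$computed_perp_distance_m,
    half_width_m = buffer_m, multiplier = multiplier, seed = seed,
    ledger = emp$ledger)
  used <- extract_covariates(landscape, qc$retained, flat_threshold)
  used$used <- 1L
  avail <- extract_covariates(landscape, av$available, flat_threshold)
  avail$used <- 0L
  common <- c("survey_id", "area_id", "x", "y", "used", "veg_code",
              "veg_class", "elevation_m", "ret_m", "timberline_dev_m",
              "slope_deg", "aspect_deg", "n_aspect", "e_aspect", "aspect_cat",
              "nonhabitat", "missing")
  rec <- rbind(used[, common], avail[, common])
  nh <- drop_nonhabitat(rec, ledger = av$ledger)
  list(records = nh$records, detection = av$detection, ledger = nh$ledger,
       qc = qc)
}

#' Parameter-recovery experiment over the full pipeline
#'
#' Simulates surveys under a known truth, runs QC, detection-adjusted
#' availability, covariate assembly and the mixed logistic fit for each
#' replicate, and summarizes bias, RMSE and 95% Wald CI coverage of the
#' estimated selection coefficients against the truth (compared on the
#' standardized scale each replicate actually fitted, an exact linear
#' reparameterization of the raw-scale truth). Optionally also runs k-fold
#' cross-validation per replicate. One landscape and transect layout is drawn
#' per experiment; replicates redraw area intercepts, observations and
#' available points. Replicate failures are recorded, not dropped silently.
#'
#' @param truth a `truth_record`.
#' @param n_replicates number of replicates.
#' @param seed master seed; replicate streams derive from it.
#' @param spec the `model_spec` to fit (default the parsimonious structure).
#' @param rows,cols,cell_size,spacing_m,inset_m,n_areas landscape / layout
#'   configuration.
#' @param veg_weights landscape composition; the default balanced mix gives
#'   every selection contrast comparable information, which keeps the
#'   Monte-Carlo error of the bias summaries well below the effects of
#'   interest (use [default_veg_weights()] for the survey-like composition).
#' @param years,used_per_km,gen_half_width_m,distance_error_sd passed to
#'   [simulate_survey()].
#' @param cv if `TRUE`, run 5-fold cross-validation per replicate and record
#'   the mean Spearman rho.
#' @param flat_threshold passed to covariate extraction.
#' @return object of class `recovery_report`: list with `summary` (data.frame
#'   per term: truth mean, estimate mean, bias, rmse, coverage), `estimates`
#'   (replicate x term), `truth_std`, `se`, `cv_rho` (per replicate, if
#'   requested), `failures`.
#' @export
recovery_experiment <- function(truth = truth_record(), n_replicates = 50,
                                seed = 1, spec = model_spec(),
                                rows = 850, cols = 620, cell_size = 30,
                                spacing_m = 500, inset_m = 300, n_areas = 8,
                                veg_weights = balanced_veg_weights(),
                                years = 2014:2017, used_per_km = 0.55,
                                gen_half_width_m = 240,
                                distance_error_sd = 20,
                                cv = FALSE, flat_threshold = 0) {
  landscape <- make_landscape(seed, rows = rows, cols = cols,
                              cell_size = cell_size,
                              veg_weights = veg_weights)
  transects <- layout_transects(landscape, spacing_m = spacing_m,
                                n_areas = n_areas, inset_m = inset_m)
  est <- se <- tru <- NULL
  cv_rho <- rep(NA_real_, n_replicates)
  n_used <- rep(NA_integer_, n_replicates)
  failures <- list()
  for (r in seq_len(n_replicates)) {
    rep_seed <- (seed %% 20000) * 100000 + r
    res <- tryCatch({
      sim <- simulate_survey(landscape, transects, truth, seed = rep_seed,
                             years = years, used_per_km = used_per_km,
                             gen_half_width_m = gen_half_width_m,
                             distance_error_sd = distance_error_sd)
      dat <- assemble_modelling_data(landscape, transects, sim$observations,
                                     sim$surveys, seed = rep_seed + 1,
                                     flat_threshold = flat_threshold)
      fit <- fit_rsf(dat$records, spec)
      ts <- truth_on_standardized_scale(truth, fit$std_params, spec)
      rho <- NA_real_
      if (cv) {
        plan <- make_fold_plan(dat$records, k = 5, seed = rep_seed + 2)
        v <- cv_boyce(dat$records, spec, plan)
        rho <- v$mean_rho
      }
      list(beta = fit$beta, se = fit$se, truth_std = ts[names(fit$beta)],
           n_used = fit$n_used, rho = rho)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        list(replicate = r, message = conditionMessage(res))
      next
    }
    if (is.null(est)) {
      est <- se <- tru <- matrix(NA_real_, n_replicates, length(res$beta),
                                 dimnames = list(NULL, names(res$beta)))
    }
    est[r, ] <- res$beta
    se[r, ] <- res$se
    tru[r, ] <- res$truth_std
    n_used[r] <- res$n_used
    cv_rho[r] <- res$rho
  }
  if (is.null(est)) stop("all replicates failed")
  ok <- !is.na(est[, 1])
  lo <- est - 1.96 * se
  hi <- est + 1.96 * se
  cover <- (tru >= lo) & (tru <= hi)
  terms <- colnames(est)[colnames(est) != "(Intercept)"]
  summary <- data.frame(
    term = terms,
    truth = colMeans(tru[ok, terms, drop = FALSE]),
    estimate = colMeans(est[ok, terms, drop = FALSE]),
    bias = colMeans(est[ok, terms, drop = FALSE] -
                      tru[ok, terms, drop = FALSE]),
    rmse = sqrt(colMeans((est[ok, terms, drop = FALSE] -
                            tru[ok, terms, drop = FALSE])^2)),
    coverage = colMeans(cover[ok, terms, drop = FALSE]),
    row.names = NULL)
  structure(list(summary = summary, estimates = est, truth_std = tru,
                 se = se, cv_rho = cv_rho, n_used = n_used,
                 n_replicates_ok = sum(ok), failures = failures),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("recovery_experiment: %d/%d replicates succeeded, mean n_used = %.0f\n",
              x$n_replicates_ok, nrow(x$estimates),
              mean(x$n_used, na.rm = TRUE)))
  cat(sprintf("  max |bias| = %.3f, coverage range %.2f-%.2f\n",
              max(abs(x$summary$bias)), min(x$summary$coverage),
              max(x$summary$coverage)))
  if (any(is.finite(x$cv_rho))) {
    cat(sprintf("  mean CV rho = %.3f\n", mean(x$cv_rho, na.rm = TRUE)))
  }
  invisible(x)
}
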