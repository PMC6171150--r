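#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with defaults anchored to
#' the survey protocol: 200-m line-buffers, 30-m deviation cutoff, 3 available
#' locations per km of effort, 500-m systematic transect spacing, 5-fold
#' cross-validation. Simulation defaults are the package's synthetic study
#' conditions (see the methods vignette).
#'
#' @param seed master seed; stage streams derive from it.
#' @param rows,cols,cell_size landscape raster size.
#' @param veg_weights landscape composition (default the survey-like
#'   composition of [default_veg_weights()]).
#' @param spacing_m,bearing,n_areas,inset_m transect layout.
#' @param years,used_per_km,gen_half_width_m,distance_error_sd survey
#'   simulation settings.
#' @param truth a `truth_record`.
#' @param buffer_m,max_deviation_m QC settings.
#' @param multiplier available locations per km of effort.
#' @param candidates list of `model_spec`s (default [candidate_set()], 24
#'   models).
#' @param k cross-validation folds.
#' @param n_bins quantile bins.
#' @param flat_threshold_deg slope at or below which aspect is "flat". The
#'   default 1 degree (rather than exactly 0) gives synthetic smooth terrain a
#'   non-empty flat class, as real elevation models have.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, rows = 850, cols = 620, cell_size = 30,
                            veg_weights = default_veg_weights(),
                            spacing_m = 500, bearing = "NS", n_areas = 8,
                            inset_m = 300, years = 2014:2017,
                            used_per_km = 0.55, gen_half_width_m = 240,
                            distance_error_sd = 20,
                            truth = truth_record(),
                            buffer_m = 200, max_deviation_m = 30,
                            multiplier = 3,
                            candidates = candidate_set(),
                            k = 5, n_bins = 10, flat_threshold_deg = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

# JSON-serializable view of a config (truth and specs flattened)
resolve_config <- function(config) {
  out <- unclass(config)
  out$truth <- unclass(config$truth)
  out$candidates <- vapply(config$candidates, spec_label, character(1))
  out
}

#' Run the analysis pipeline end to end
#'
#' Stages, in order: `simulate` (landscape, transects, surveys,
#' observations), `qc` (buffer + deviation filters, empty-survey removal),
#' `availability` (detection-adjusted available locations and covariate
#' assembly), `fit` (candidate models, AIC selection with the parsimony
#' rule), `validate` (stratified k-fold cross-validation of the selected
#' model), `map` (raster-wide RSF, quantile bins from the modelling sample,
#' coverage summaries, area-adjusted validation of the used locations).
#' Later stages require the earlier ones; omitted stages simply leave their
#' outputs out. Reruns with the same config reproduce all stochastic outputs
#' bit for bit.
#'
#' @param config a [pipeline_config()].
#' @param stages character vector of stages to run.
#' @param out_dir optional directory: artifacts (resolved config, ledger,
#'   tables, detection fit, selected-model JSON, map grids) are written there
#'   as plain text/CSV.
#' @param progress print stage progress.
#' @return list with `landscape`, `transects`, `surveys`, `observations`,
#'   `ledger`, `records`, `detection`, `selection`, `fit`, `cv`, `map`,
#'   `coverage`, `area_adjusted`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "qc", "availability", "fit",
                                    "validate", "map"),
                         out_dir = NULL, progress = FALSE) {
  say <- function(...) if (progress) message(sprintf(...))
  want <- function(s) s %in% stages
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(name, writer) {
    if (!is.null(out_dir)) writer(file.path(out_dir, name))
  }
  emit("config.json", function(p) {
    jsonlite::write_json(resolve_config(config), p, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
  })
  out <- list(config = config)

  say("simulate: landscape, transects, surveys")
  landscape <- make_landscape(config$seed, rows = config$rows,
                              cols = config$cols,
                              cell_size = config$cell_size,
                              veg_weights = config$veg_weights)
  transects <- layout_transects(landscape, spacing_m = config$spacing_m,
                                bearing = config$bearing,
                                n_areas = config$n_areas,
                                inset_m = config$inset_m)
  sim <- simulate_survey(landscape, transects, config$truth,
                         seed = (config$seed %% 20000) * 100000 + 11,
                         years = config$years,
                         used_per_km = config$used_per_km,
                         gen_half_width_m = config$gen_half_width_m,
                         distance_error_sd = config$distance_error_sd)
  out$landscape <- landscape
  out$transects <- transects
  out$surveys <- sim$surveys
  out$observations <- sim$observations
  emit("observations.csv", function(p) write_table_csv(sim$observations, p))
  emit("surveys.csv", function(p) write_table_csv(sim$surveys, p))
  emit("transects.csv", function(p) write_transects(transects, p))
  if (!any(want(c("qc", "availability", "fit", "validate", "map")))) {
    return(invisible(out))
  }

  say("qc + availability: %d observations", nrow(sim$observations))
  dat <- assemble_modelling_data(
    landscape, transects, sim$observations, sim$surveys,
    seed = (config$seed %% 20000) * 100000 + 12,
    buffer_m = config$buffer_m, max_deviation_m = config$max_deviation_m,
    multiplier = config$multiplier,
    flat_threshold = config$flat_threshold_deg)
  out$ledger <- dat$ledger
  out$records <- dat$records
  out$detection <- dat$detection
  emit("ledger.csv", function(p) write_table_csv(dat$ledger, p))
  emit("detection.txt", function(p) write_detection(dat$detection, p))
  emit("records.csv", function(p) write_table_csv(dat$records, p))
  if (!any(want(c("fit", "validate", "map")))) return(invisible(out))

  say("fit: %d candidate models on %d records", length(config$candidates),
      nrow(dat$records))
  std <- fit_standardization(dat$records)
  fits <- lapply(config$candidates, function(sp) {
    tryCatch(fit_rsf(dat$records, sp, std_params = std),
             error = function(e) {
               warning(sprintf("candidate '%s' failed: %s", spec_label(sp),
                               conditionMessage(e)))
               NULL
             })
  })
  fits <- fits[!vapply(fits, is.null, logical(1))]
  sel <- select_model(fits)
  out$selection <- sel$table
  out$fit <- sel$fit
  emit("model_selection.csv", function(p) write_table_csv(sel$table, p))
  emit("fit.json", function(p) write_fit_json(sel$fit, p))

  if (want("validate")) {
    say("validate: %d-fold cross-validation", config$k)
    plan <- make_fold_plan(dat$records, k = config$k,
                           seed = (config$seed %% 20000) * 100000 + 13)
    out$cv <- cv_boyce(dat$records, sel$fit$spec, plan,
                       n_bins = config$n_bins)
    emit("cv.csv", function(p) write_table_csv(out$cv$per_fold, p))
  }
  if (want("map")) {
    say("map: raster-wide RSF")
    w_model <- predict_rsf(sel$fit, dat$records)
    edges <- quantile_bin(w_model[is.finite(w_model)],
                          config$n_bins)$edges
    bm <- map_rsf(sel$fit, landscape, bin_edges = edges,
                  flat_threshold = config$flat_threshold_deg)
    mask <- buffer_mask(landscape, transects, config$buffer_m)
    used_pts <- dat$records[dat$records$used == 1, c("x", "y")]
    out$map <- bm
    out$coverage <- summarize_bin_coverage(bm, mask, used_pts)
    out$area_adjusted <- area_adjusted_validation(used_pts, bm)
    emit("coverage.csv", function(p) write_table_csv(out$coverage, p))
    emit("rsf_scaled.grid", function(p) {
      write_grid(bm$rsf, p, origin = landscape$origin,
                 cellsize = landscape$cellsize)
    })
    emit("rsf_bins.grid", function(p) {
      write_grid(bm$bin, p, origin = landscape$origin,
                 cellsize = landscape$cellsize)
    })
  }
  invisible(out)
}

#' Serialize a fitted model to JSON
#'
#' @param fit an `rsf_fit`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(
    model = spec_label(fit$spec),
    beta = as.list(fit$beta), se = as.list(stats::setNames(fit$se,
                                                           names(fit$beta))),
    ranef_var = fit$ranef_var, loglik = fit$loglik, aic = fit$aic, K = fit$K,
    n_used = fit$n_used, n_available = fit$n_available,
    standardization = lapply(fit$std_params, as.list))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load the packaged survey-composition fixture
#'
#' Category counts of used and available locations from the national
#' 2014--2017 line-transect dataset: per vegetation class, per aspect
#' category, and above/below the timberline. Totals are validated on load
#' (12,146 used and 38,149 available locations).
#'
#' @return data.frame with `variable`, `category`, `used`, `available`, of
#'   class `table2_fixture`.
#' @export
load_survey_composition <- function() {
  path <- system.file("extdata", "survey_composition.csv",
                      package = "ptarmiganRSF", mustWork = TRUE)
  fx <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (v in unique(fx$variable)) {
    u <- sum(fx$used[fx$variable == v])
    a <- sum(fx$available[fx$variable == v])
    if (u != 12146L) {
      stop(sprintf("fixture validation: %s used total is %d, expected 12146",
                   v, u))
    }
    if (a != 38149L) {
      stop(sprintf(
        "fixture validation: %s available total is %d, expected 38149", v, a))
    }
  }
  structure(fx, class = c("table2_fixture", "data.frame"))
}

#' Summaries and naive selection ratios from the composition fixture
#'
#' Totals plus, per vegetation class, the naive selection ratio
#' `(used_k / used_total) / (available_k / available_total)` -- an exploratory
#' display of which classes are over- or under-represented among used
#' locations, not the mixed-model estimate.
#'
#' @param fixture output of [load_survey_composition()].
#' @return list with `used_total`, `available_total`, `vegetation`
#'   (data.frame with a `naive_ratio` column, ordered by ratio).
#' @export
fixture_summary <- function(fixture = load_survey_composition()) {
  veg <- fixture[fixture$variable == "vegetation", ]
  used_total <- sum(veg$used)
  available_total <- sum(veg$available)
  veg$naive_ratio <- (veg$used / used_total) /
    (veg$available / available_total)
  veg <- veg[order(-veg$naive_ratio),
             c("category", "used", "available", "naive_ratio")]
  rownames(veg) <- NULL
  list(used_total = used_total, available_total = available_total,
       vegetation = veg)
}
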