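#' Specify a candidate selection model
#'
#' Every candidate model contains vegetation type (16 classes, reference =
#' Exposed alpine ridges). Deviation from the timberline and slope can enter
#' linearly or with an added quadratic term (quadratic requires linear);
#' aspect can enter as the five-level categorical variable (reference = flat),
#' as north--south exposure only, or as north--south plus east--west exposure.
#' Quadratic terms are squares of the standardized value.
#'
#' @param timberline `"none"`, `"linear"` or `"quadratic"`.
#' @param slope `"none"`, `"linear"` or `"quadratic"`.
#' @param aspect `"none"`, `"categorical"`, `"ns"` or `"ns_ew"`.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(timberline = c("quadratic", "linear", "none"),
                       slope = c("quadratic", "linear", "none"),
                       aspect = c("none", "categorical", "ns", "ns_ew")) {
  spec <- list(timberline = match.arg(timberline), slope = match.arg(slope),
               aspect = match.arg(aspect))
  structure(spec, class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(spec_label(x), "\n")
  invisible(x)
}

#' Human-readable label for a model spec
#'
#' @param spec a `model_spec`.
#' @return character scalar, e.g.
#'   `"Vegetation + Timberline + Timberline^2 + Slope + Slope^2"`.
#' @export
spec_label <- function(spec) {
  parts <- "Vegetation"
  if (spec$timberline != "none") parts <- c(parts, "Timberline")
  if (spec$timberline == "quadratic") parts <- c(parts, "Timberline^2")
  if (spec$slope != "none") parts <- c(parts, "Slope")
  if (spec$slope == "quadratic") parts <- c(parts, "Slope^2")
  parts <- c(parts, switch(spec$aspect, none = NULL,
                           categorical = "Aspect categorical",
                           ns = "Aspect N-S",
                           ns_ew = c("Aspect N-S", "Aspect E-W")))
  paste(parts, collapse = " + ")
}

# fixed-effect terms of a spec, in design order
spec_terms <- function(spec) {
  t <- "veg_class"
  if (spec$timberline != "none") t <- c(t, "timberline_dev_m_z")
  if (spec$timberline == "quadratic") t <- c(t, "I(timberline_dev_m_z^2)")
  if (spec$slope != "none") t <- c(t, "slope_deg_z")
  if (spec$slope == "quadratic") t <- c(t, "I(slope_deg_z^2)")
  t <- c(t, switch(spec$aspect, none = NULL, categorical = "aspect_cat",
                   ns = "n_aspect_z", ns_ew = c("n_aspect_z", "e_aspect_z")))
  t
}

# error if a declared factor level never occurs in the data
check_levels <- function(records, spec) {
  for (v in c("veg_class", if (spec$aspect == "categorical") "aspect_cat")) {
    tab <- table(records[[v]])
    absent <- names(tab)[tab == 0]
    if (length(absent)) {
      stop(sprintf("factor level absent from data: %s = '%s'",
                   v, paste(absent, collapse = "', '")))
    }
  }
}

#' Build the used-available design for a model spec
#'
#' Treatment coding with Exposed alpine ridges as the vegetation reference and
#' flat as the aspect reference; columns ordered intercept, 15 vegetation
#' dummies, then the continuous/aspect terms of the spec. Records must carry
#' standardized (`_z`) covariate columns and a 0/1 `used` response.
#'
#' @param records standardized covariate records with `used` and `area_id`.
#' @param spec a `model_spec`.
#' @return list with `y` (0/1 response), `X` (fixed-effects model matrix),
#'   `groups` (survey-area labels).
#' @export
build_design <- function(records, spec) {
  check_levels(records, spec)
  X <- stats::model.matrix(stats::reformulate(spec_terms(spec)),
                           data = records)
  list(y = records$used, X = X, groups = records$area_id)
}

#' Fit the mixed-effects used-available logistic regression
#'
#' Maximizes the Laplace-approximated marginal likelihood of a logistic
#' regression of used (1) versus available (0) locations with a random
#' intercept per survey area, which absorbs between-area density differences.
#' The parameter count `K` is the number of fixed effects plus one for the
#' random-intercept variance, and `AIC = -2 logLik + 2 K`.
#'
#' @param y 0/1 response.
#' @param X fixed-effects model matrix (first column the intercept).
#' @param groups grouping labels (>= 2 distinct values).
#' @param spec the `model_spec` that produced `X` (stored on the fit).
#' @param control a [lme4::glmerControl()]; the default uses nloptwrap and
#'   skips the finite-difference derivative check for speed.
#' @return object of class `rsf_fit`: `beta` (named fixed effects), `se`,
#'   `vcov`, `ranef_var` (random-intercept variance), `loglik`, `aic`, `K`,
#'   `n_used`, `n_available`, `converged`, `spec`, `std_params` (filled by
#'   [fit_rsf()]).
#' @export
fit_mixed_logistic <- function(y, X, groups, spec = NULL, control = NULL) {
  if (length(unique(groups)) < 2) {
    stop("need >= 2 groups to estimate the random-intercept variance")
  }
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient; check for separation or ",
         "collinear terms")
  }
  if (is.null(control)) {
    control <- lme4::glmerControl(optimizer = "nloptwrap",
                                  calc.derivs = FALSE)
  }
  df <- data.frame(.y = y, .g = factor(groups))
  fit <- lme4::glmer(.y ~ 0 + X + (1 | .g), data = df,
                     family = stats::binomial(), control = control)
  beta <- lme4::fixef(fit)
  names(beta) <- sub("^X", "", names(beta))
  V <- as.matrix(stats::vcov(fit))
  dimnames(V) <- list(names(beta), names(beta))
  K <- length(beta) + 1L
  ll <- as.numeric(stats::logLik(fit))
  msgs <- fit@optinfo$conv$lme4$messages
  structure(list(
    beta = beta, se = sqrt(diag(V)), vcov = V,
    ranef_var = as.numeric(lme4::VarCorr(fit)$.g),
    loglik = ll, aic = -2 * ll + 2 * K, K = K,
    n_used = sum(y == 1), n_available = sum(y == 0),
    converged = fit@optinfo$conv$opt == 0 && is.null(msgs),
    messages = msgs, spec = spec, std_params = NULL),
    class = "rsf_fit")
}

#' @export
print.rsf_fit <- function(x, ...) {
  cat("Used-available mixed logistic fit",
      if (!is.null(x$spec)) paste0("(", spec_label(x$spec), ")"), "\n")
  cat(sprintf("  n used = %d, n available = %d, K = %d, AIC = %.2f\n",
              x$n_used, x$n_available, x$K, x$aic))
  cat(sprintf("  random-intercept variance (survey area) = %.4f\n",
              x$ranef_var))
  invisible(x)
}

#' Fit a candidate model on covariate records
#'
#' High-level wrapper: checks factor levels, fits (or re-uses) the
#' standardization on the combined used + available records, builds the
#' design, fits the mixed logistic model, and stores the standardization with
#' the fit so later predictions use identical scaling.
#'
#' @param records modelling records (post non-habitat removal) with raw
#'   covariates, `used` and `area_id`.
#' @param spec a `model_spec`.
#' @param std_params optional pre-fitted `standardization_params`.
#' @param control passed to [fit_mixed_logistic()].
#' @return an `rsf_fit` carrying `std_params`.
#' @export
fit_rsf <- function(records, spec = model_spec(), std_params = NULL,
                    control = NULL) {
  if (is.null(std_params)) std_params <- fit_standardization(records)
  rec <- apply_standardization(records, std_params)
  d <- build_design(rec, spec)
  fit <- fit_mixed_logistic(d$y, d$X, d$groups, spec = spec,
                            control = control)
  fit$std_params <- std_params
  fit
}

#' Enumerate the candidate model set
#'
#' Cartesian grid over the term options, always including vegetation type.
#' The default grid -- timberline \{none, linear, linear+quadratic\} x slope
#' \{none, linear+quadratic\} x aspect \{none, categorical, N-S, N-S+E-W\} --
#' has 24 members and contains the four top published model structures as
#' well as the vegetation-only model. Duplicate specs are collapsed with a
#' warning.
#'
#' @param timberline_opts,slope_opts,aspect_opts character vectors of options
#'   (see [model_spec()]); empty vectors mean the term is left out.
#' @return list of `model_spec`s.
#' @export
candidate_set <- function(timberline_opts = c("none", "linear", "quadratic"),
                          slope_opts = c("none", "quadratic"),
                          aspect_opts = c("none", "categorical", "ns",
                                          "ns_ew")) {
  if (!length(timberline_opts)) timberline_opts <- "none"
  if (!length(slope_opts)) slope_opts <- "none"
  if (!length(aspect_opts)) aspect_opts <- "none"
  g <- expand.grid(timberline = timberline_opts, slope = slope_opts,
                   aspect = aspect_opts, stringsAsFactors = FALSE)
  specs <- lapply(seq_len(nrow(g)), function(i) {
    model_spec(g$timberline[i], g$slope[i], g$aspect[i])
  })
  labels <- vapply(specs, spec_label, character(1))
  if (anyDuplicated(labels)) {
    warning("duplicate model specs collapsed")
    specs <- specs[!duplicated(labels)]
  }
  specs
}

#' Select a model by AIC with the parsimony rule
#'
#' Models within `delta` AIC units of the best are treated as statistically
#' equivalent; among them the least complex (smallest `K`) is selected, ties
#' on `K` broken by lower AIC.
#'
#' @param fits list of `rsf_fit`s (>= 1 converged).
#' @param delta equivalence threshold (default 2).
#' @return list with `fit` (the chosen `rsf_fit`), `index`, and `table`
#'   (data.frame: Model, K, AIC, dAIC, weight, ordered by AIC).
#' @export
select_model <- function(fits, delta = 2) {
  ok <- vapply(fits, function(f) is.finite(f$aic), logical(1))
  if (!any(ok)) stop("no converged fits to select from")
  fits <- fits[ok]
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  K <- vapply(fits, `[[`, numeric(1), "K")
  daic <- aic - min(aic)
  w <- exp(-daic / 2); w <- w / sum(w)
  cand <- which(daic < delta)
  best <- cand[order(K[cand], aic[cand])][1]
  tab <- data.frame(
    Model = vapply(fits, function(f) spec_label(f$spec), character(1)),
    K = K, AIC = aic, dAIC = daic, weight = w)
  tab <- tab[order(tab$AIC), ]
  rownames(tab) <- NULL
  list(fit = fits[[best]], index = best, table = tab)
}

#' Predict the exponential RSF at covariate records
#'
#' The relative probability of selection `w(x) = exp(beta_1 x_1 + ... +
#' beta_n x_n)` over the fixed effects, excluding the intercept and the random
#' intercepts (predictions are marginal and portable beyond the surveyed
#' areas). Raw covariates are standardized with the parameters stored on the
#' fit. Non-habitat or missing records yield `NA`.
#'
#' @param fit an `rsf_fit` from [fit_rsf()] (must carry `std_params`).
#' @param records covariate records (raw scale).
#' @return numeric vector of strictly positive RSF values (`NA` for
#'   non-habitat/missing records).
#' @export
predict_rsf <- function(fit, records) {
  if (is.null(fit$std_params)) {
    stop("fit carries no standardization parameters; refit with fit_rsf() ",
         "so predictions are standardized identically to the training data")
  }
  rec <- apply_standardization(records, fit$std_params)
  ok <- !is.na(rec$veg_class) & rec$veg_class %in% VEG_LEVELS
  if (!is.null(rec$nonhabitat)) ok <- ok & !rec$nonhabitat
  if (!is.null(rec$missing)) ok <- ok & !rec$missing
  out <- rep(NA_real_, nrow(rec))
  if (!any(ok)) return(out)
  sub <- rec[ok, , drop = FALSE]
  sub$veg_class <- factor(as.character(sub$veg_class), levels = VEG_LEVELS)
  X <- stats::model.matrix(stats::reformulate(spec_terms(fit$spec)),
                           data = sub)
  if (!identical(colnames(X), names(fit$beta))) {
    stop("prediction design does not match the fitted terms")
  }
  keep <- colnames(X) != "(Intercept)"
  out[ok] <- exp(as.vector(X[, keep, drop = FALSE] %*% fit$beta[keep]))
  out
}

#' Scale RSF values to (0, 1]
#'
#' Divides by the maximum, preserving order; the maximum becomes exactly 1.
#'
#' @param values positive RSF values (`NA` allowed and preserved).
#' @return scaled values.
#' @export
scale_rsf <- function(values) {
  m <- suppressWarnings(max(values, na.rm = TRUE))
  if (!is.finite(m)) stop("no finite RSF values to scale")
  values / m
}

#' Quantile-bin RSF values
#'
#' Computes the interior empirical quantile cut points (deciles for
#' `n_bins = 10`) of a binning sample and assigns every value a bin rank from
#' 1 (low relative probability of selection) to `n_bins` (high). Heavy ties
#' that collapse cut points trigger a warning and leave degenerate (empty)
#' bins.
#'
#' @param values binning sample (finite).
#' @param n_bins number of bins (>= 2).
#' @return object of class `bin_assignment`: list with `edges` (interior cut
#'   points), `n_bins`, and `bin` (bin index per input value).
#' @export
quantile_bin <- function(values, n_bins = 10) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  v <- values[is.finite(values)]
  if (!length(v)) stop("no finite values to bin")
  if (length(unique(v)) < n_bins) {
    warning("fewer distinct values than bins; degenerate bins possible")
  }
  edges <- unname(stats::quantile(v, probs = seq_len(n_bins - 1) / n_bins))
  if (anyDuplicated(edges)) {
    warning("tied quantile cut points: some bins collapse")
  }
  structure(list(edges = edges, n_bins = n_bins,
                 bin = bin_values(values, edges)),
            class = "bin_assignment")
}

#' Assign values to bins given interior cut points
#'
#' Monotone assignment: bin `k` is the half-open interval between cut points
#' `k-1` (exclusive at the lower end via `<=` on the edge) and `k`.
#'
#' @param values numeric values (`NA` gives `NA`).
#' @param edges nondecreasing interior cut points (length `n_bins - 1`).
#' @return integer bin indices 1..`length(edges) + 1`.
#' @export
bin_values <- function(values, edges) {
  out <- findInterval(values, edges) + 1L
  out[!is.finite(values)] <- NA_integer_
  out
}
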