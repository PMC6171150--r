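test_that("design matrices have the documented structure", {
  rec <- toy_records()
  rec <- apply_standardization(rec, fit_standardization(rec))
  # vegetation + timberline + timberline^2 + slope + slope^2
  d <- build_design(rec, model_spec())
  expect_equal(ncol(d$X), 20)  # 1 + 15 + 4
  expect_equal(colnames(d$X)[1], "(Intercept)")
  # adding categorical aspect: +4 dummies, flat as reference
  d2 <- build_design(rec, model_spec(aspect = "categorical"))
  expect_equal(ncol(d2$X), 24)
  # a reference-class record with centred continuous terms is (1, 0, ..., 0)
  ref <- rec[1, ]
  ref$veg_class <- factor("Exposed alpine ridges", levels = VEG_LEVELS)
  ref$timberline_dev_m_z <- 0
  ref$slope_deg_z <- 0
  row <- build_design(rbind(ref, rec[2:20, ]), model_spec())$X[1, ]
  expect_equal(unname(row), c(1, rep(0, 19)))
})

test_that("an absent factor level is reported by name", {
  rec <- toy_records()
  rec <- apply_standardization(rec, fit_standardization(rec))
  rec2 <- rec[rec$veg_class != "Herb-rich meadows", ]
  expect_error(build_design(rec2, model_spec()), "Herb-rich meadows")
})

test_that("the parsimonious model structure counts 21 parameters and the
           AIC identity holds exactly", {
  out <- small_pipeline()
  fit <- out$fit
  expect_equal(fit$K, 21)  # 20 fixed effects + random-intercept variance
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$K)
})

test_that("with no between-group variance the GLMM matches plain logistic
           regression", {
  set.seed(61)
  n <- 4000
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.4 + 0.8 * x1 - 0.5 * x2))
  g <- sample(letters[1:4], n, replace = TRUE)  # no group effect simulated
  X <- cbind("(Intercept)" = 1, x1 = x1, x2 = x2)
  fit <- fit_mixed_logistic(y, X, g)
  ref <- glm(y ~ x1 + x2, family = binomial())
  expect_lt(max(abs(fit$beta - coef(ref))), 1e-3)
  expect_lt(fit$ranef_var, 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
})

test_that("Laplace log-likelihood agrees with adaptive-quadrature integration
           on a two-group dataset", {
  set.seed(62)
  n_per <- 150
  g <- rep(c("g1", "g2"), each = n_per)
  b <- rep(c(-0.8, 0.8), each = n_per)
  x <- rnorm(2 * n_per)
  y <- rbinom(2 * n_per, 1, plogis(0.2 + 0.6 * x + b))
  X <- cbind("(Intercept)" = 1, x = x)
  fit <- fit_mixed_logistic(y, X, g)
  oracle <- oracle_marginal_loglik(y, X, g, fit$beta, fit$ranef_var)
  expect_lt(abs(fit$loglik - oracle), 0.05)
})

test_that("model selection applies the delta-AIC parsimony rule", {
  mk <- function(aic, K, label) {
    structure(list(aic = aic, K = K, loglik = -(aic - 2 * K) / 2,
                   spec = model_spec()), class = "rsf_fit")
  }
  # equivalent fits (dAIC = 0.35): the less complex one wins
  sel <- select_model(list(mk(53190.30, 25), mk(53190.65, 21)))
  expect_equal(sel$fit$K, 21)
  expect_equal(sel$table$dAIC[2], 0.35, tolerance = 1e-9)
  # a single fit selects itself
  expect_equal(select_model(list(mk(100, 5)))$index, 1)
  # beyond the threshold the lower-AIC model wins regardless of K
  sel3 <- select_model(list(mk(100, 25), mk(103, 4)))
  expect_equal(sel3$fit$K, 25)
  # ties on K break by AIC
  sel4 <- select_model(list(mk(100.5, 7), mk(100.0, 7)))
  expect_equal(sel4$fit$aic, 100.0)
})

test_that("the default candidate grid has 24 specs including the published
           structures, all carrying vegetation", {
  cs <- candidate_set()
  expect_equal(length(cs), 24)
  labels <- vapply(cs, spec_label, character(1))
  expect_true("Vegetation + Timberline + Timberline^2 + Slope + Slope^2 + Aspect categorical"
              %in% labels)
  expect_true("Vegetation + Timberline + Timberline^2 + Slope + Slope^2"
              %in% labels)
  expect_true("Vegetation + Timberline + Timberline^2 + Slope + Slope^2 + Aspect N-S"
              %in% labels)
  expect_true("Vegetation" %in% labels)
  expect_true(all(startsWith(labels, "Vegetation")))
  # empty option grid collapses to the vegetation-only model
  expect_equal(spec_label(candidate_set(character(), character(),
                                        character())[[1]]), "Vegetation")
})

test_that("RSF predictions exponentiate the no-intercept linear predictor", {
  out <- small_pipeline()
  fit <- out$fit
  rec <- out$records
  # reference-class record at standardized zero has w = 1 (empty sum)
  ref <- rec[1, ]
  ref$veg_class <- factor("Exposed alpine ridges", levels = VEG_LEVELS)
  ref$timberline_dev_m <- fit$std_params$timberline_dev_m[["mean"]]
  ref$slope_deg <- fit$std_params$slope_deg[["mean"]]
  expect_equal(predict_rsf(fit, ref), 1, tolerance = 1e-12)
  # linear-algebra oracle on a sample of records
  sub <- rec[seq(1, nrow(rec), by = 7), ]
  z <- apply_standardization(sub, fit$std_params)
  X <- model.matrix(~ veg_class + timberline_dev_m_z +
                      I(timberline_dev_m_z^2) + slope_deg_z +
                      I(slope_deg_z^2), z)
  manual <- exp(as.vector(X[, -1] %*% fit$beta[-1]))
  expect_equal(unname(predict_rsf(fit, sub)), unname(manual),
               tolerance = 1e-12)
  expect_true(all(predict_rsf(fit, sub) > 0))
  # monotonicity in a positive coefficient
  b_herb <- fit$beta[["veg_classHerb-rich meadows"]]
  herb <- ref; herb$veg_class <- factor("Herb-rich meadows",
                                        levels = VEG_LEVELS)
  expect_equal(predict_rsf(fit, herb), exp(b_herb), tolerance = 1e-12)
  # a fit without standardization parameters refuses to predict
  bare <- fit; bare$std_params <- NULL
  expect_error(predict_rsf(bare, sub), "standardization")
})

test_that("max-scaling and quantile binning behave as specified", {
  expect_equal(scale_rsf(c(2, 4, 8)), c(0.25, 0.5, 1))
  expect_equal(scale_rsf(c(3, 3, 3)), c(1, 1, 1))
  v <- runif(50)
  expect_equal(order(scale_rsf(v)), order(v))
  expect_error(scale_rsf(c(NA_real_, NA_real_)), "finite")

  qb <- quantile_bin(1:100)
  expect_equal(qb$bin[1:10], rep(1L, 10))
  expect_equal(qb$bin[91:100], rep(10L, 10))
  expect_equal(as.vector(table(qb$bin)), rep(10L, 10))
  # each bin holds 10% +/- 1 of a continuous sample
  set.seed(63)
  v <- rlnorm(1000)
  tab <- table(quantile_bin(v)$bin)
  expect_true(all(abs(tab - 100) <= 1))
  # monotone: larger value, same-or-larger bin
  o <- order(v)
  expect_true(all(diff(quantile_bin(v)$bin[o]) >= 0))
  w <- capture_warnings(quantile_bin(rep(1, 30)))
  expect_match(w, "distinct", all = FALSE)
  expect_match(w, "tied", all = FALSE)
})
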