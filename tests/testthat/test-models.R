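make_toy_data <- function(n = 5000, seed = 1) {
  cfg <- toy_linear_config(n, seed = seed)
  generate_cohort(cfg)
}

test_that("outcome model recovers the generating wave coefficient", {
  cfg <- toy_linear_config(5000, p0 = 0.4, p1 = 0.4, b_wave = -2, b_m = 0,
                           seed = 21)
  d <- generate_cohort(cfg)
  spec <- mediation_spec("ht_low", mediators = "smoking")
  fit <- fit_outcome_model(d, spec, xm_interactions = FALSE)
  b <- fit$coefficients["wave"]
  se <- sqrt(diag(fit$vcov))["wave"]
  expect_lt(abs(b - (-2)), 3 * se)
  expect_equal(fit$family, "gaussian linear")
  expect_equal(fit$n_obs, nrow(d))
  # covariance symmetric and positive semi-definite
  expect_equal(fit$vcov, t(fit$vcov), tolerance = 1e-12)
  expect_gte(min(eigen(fit$vcov, symmetric = TRUE)$values), -1e-12)
})

test_that("a duplicated design column raises a rank-deficiency error", {
  d <- make_toy_data(500)
  d$sex_copy <- d$sex
  spec <- mediation_spec("ht_low", mediators = "smoking",
                         covariates = c("age", "sex", "sex_copy"))
  expect_error(fit_outcome_model(d, spec), "collinear")
})

test_that("OLS residuals are orthogonal to the design", {
  d <- make_toy_data(2000, seed = 4)
  spec <- mediation_spec("ht_low", mediators = "smoking")
  fit <- fit_outcome_model(d, spec)
  X <- model.matrix(fit$fit)
  r <- residuals(fit$fit)
  expect_lt(max(abs(crossprod(X, r))) / nrow(X), 1e-8)
})

test_that("categorical model recovers a known wave slope and normalises
          probabilities", {
  p0 <- plogis(0); p1 <- plogis(1.2)
  cfg <- toy_linear_config(20000, p0 = p0, p1 = p1, seed = 31)
  d <- generate_cohort(cfg)
  fit <- fit_categorical_model(d, "smoking", predictors = c("wave"))
  b <- fit$coefficients["wave"]
  se <- sqrt(diag(vcov(fit$fit)))["wave"]
  expect_lt(abs(b - 1.2), 3 * se)
  pr <- predict_probs(fit, d[1:50, ])
  expect_true(all(pr >= 0 & pr <= 1))
  expect_lt(max(abs(rowSums(pr) - 1)), 1e-10)
  # slopes near zero when the target does not depend on the predictors
  cfg0 <- toy_linear_config(20000, p0 = 0.4, p1 = 0.4, seed = 32)
  fit0 <- fit_categorical_model(generate_cohort(cfg0), "smoking",
                                predictors = c("wave", "sex"))
  z <- fit0$coefficients[c("wave", "sex")] /
    sqrt(diag(vcov(fit0$fit)))[c("wave", "sex")]
  expect_true(all(abs(z) < 3))
})

test_that("spline-vs-linear age test: nesting, degrees of freedom, power", {
  d <- generate_cohort(hunt_config(n_per_wave = 1250, seed = 8,
                                   missingness_rate = 0))
  spec <- mediation_spec("ht_low",
                         mediators = c("ear_infections", "noise", "smoking"))
  lrt <- lrt_spline_vs_linear(d, spec)
  expect_gte(lrt$statistic, 0)
  expect_equal(lrt$df, 3)
  # the default generator has a genuinely curved age effect
  expect_lt(lrt$p_value, 1e-3)
  # under a strictly linear age effect the statistic stays modest
  cfg_lin <- toy_linear_config(2000, seed = 9)
  lrt0 <- lrt_spline_vs_linear(generate_cohort(cfg_lin),
                               mediation_spec("ht_low", mediators = "smoking"))
  expect_gte(lrt0$statistic, 0)
  expect_true(lrt0$p_value > 0 && lrt0$p_value <= 1)
})

test_that("spline model log-likelihood dominates the nested linear model", {
  for (s in 1:3) {
    d <- generate_cohort(hunt_config(n_per_wave = 400, seed = s,
                                     missingness_rate = 0))
    spec <- mediation_spec("ht_high",
                           mediators = c("ear_infections", "smoking"))
    f1 <- fit_outcome_model(d, spec, age_spline = TRUE)
    f0 <- fit_outcome_model(d, spec, age_spline = FALSE)
    expect_gte(f1$logLik, f0$logLik - 1e-8)
  }
})
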