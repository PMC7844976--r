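test_that("imputation estimator recovers the product-of-coefficients truth
          in a linear single-mediator system", {
  cfg <- toy_linear_config(10000, seed = 51)
  truth <- true_effects(cfg, "ht_low")$nie_joint        # 0.4
  d <- generate_cohort(cfg)
  spec <- mediation_spec("ht_low", mediators = "smoking")
  res <- estimate_joint_nie(d, spec, bootstrap = 100, seed = 1)
  expect_lt(abs(res$nie - truth), 3 * res$se["nie"])
  expect_true(res$ci["nie", 1] < res$nie && res$nie < res$ci["nie", 2])
})

test_that("no indirect effect when mediators are independent of exposure", {
  cfg <- toy_linear_config(10000, p0 = 0.4, p1 = 0.4, seed = 52)
  d <- generate_cohort(cfg)
  spec <- mediation_spec("ht_low", mediators = "smoking")
  res <- estimate_joint_nie(d, spec, bootstrap = 100, seed = 2)
  expect_lt(abs(res$nie), 3 * res$se["nie"])
})

test_that("NDE + NIE equals the total effect to numerical precision", {
  for (s in 1:4) {
    cfg <- if (s %% 2) toy_two_mediator_config(800, seed = s)
           else toy_linear_config(800, wave_x_m = 1.0, seed = s)
    d <- generate_cohort(cfg)
    res <- estimate_joint_nie(d, joint_spec_for(cfg))
    expect_lt(abs(res$nde + res$nie - res$total_effect), 1e-8)
  }
  d <- generate_cohort(hunt_config(n_per_wave = 600, missingness_rate = 0))
  spec <- mediation_spec("ht_high",
    mediators = c("education", "ear_infections", "noise", "smoking"))
  res <- estimate_joint_nie(d, spec)
  expect_lt(abs(res$nde + res$nie - res$total_effect), 1e-8)
})

test_that("difference method coincides with the natural effect model in
          linear no-interaction systems", {
  cfg <- toy_linear_config(10000, seed = 53)
  d <- generate_cohort(cfg)
  spec <- mediation_spec("ht_low", mediators = "smoking")
  ne <- estimate_joint_nie(d, spec, bootstrap = 100, seed = 3)
  dm <- difference_method(d, spec)
  expect_lt(abs(ne$nie - dm$nie), 0.05)
  expect_lt(abs(dm$nie - 0.4), 3 * ne$se["nie"])
  # and diverges under a strong exposure-mediator interaction (a rare
  # mediator whose harmful effect strengthens in the second wave)
  cfgx <- toy_linear_config(10000, p0 = 0.1, p1 = 0.5, b_m = 1.0,
                            wave_x_m = 2.5, seed = 54)
  dx <- generate_cohort(cfgx)
  nex <- estimate_joint_nie(dx, spec, bootstrap = 100, seed = 4)
  dmx <- difference_method(dx, spec, bootstrap = 100, seed = 5)
  gap_se <- sqrt(nex$se["nie"]^2 + dmx$se["nie"]^2)
  expect_gt(abs(nex$nie - dmx$nie), 3 * gap_se)
})

test_that("mediated proportion arithmetic and guards", {
  expect_equal(mediated_proportion(-5, 0), 0)
  expect_equal(round(mediated_proportion(-2.5, -0.5), 2), 0.2)
  expect_error(mediated_proportion(0, -0.5), "zero")
})

test_that("stratified estimation filters by sex and drops it as covariate", {
  d <- generate_cohort(hunt_config(n_per_wave = 1500, missingness_rate = 0))
  specw <- mediation_spec("ht_low", mediators = c("noise", "smoking"),
                          stratum = "women")
  res <- estimate_joint_nie(d, specw)
  expect_equal(res$n_used, sum(d$sex == 0))
  expect_false("sex" %in% specw$covariates)
  expect_error(estimate_joint_nie(d[d$sex == 1, ], specw), "empty stratum")
})

test_that("estimators demand complete data and a binary exposure", {
  d <- generate_cohort(hunt_config(n_per_wave = 300, missingness_rate = 0.2))
  spec <- mediation_spec("ht_low", mediators = c("noise", "smoking"))
  expect_error(estimate_joint_nie(d, spec), "listwise_delete")
  d2 <- listwise_delete(d, spec)$data
  d2$wave[1] <- 2
  expect_error(estimate_joint_nie(d2, spec), "0/1")
  expect_error(estimate_joint_nie(d2, mediation_spec("ht_low",
    mediators = "absent_column")), "absent")
})
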