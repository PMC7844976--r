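test_that("the curve at rho = 0 reproduces the unadjusted estimate and is
          continuous in rho", {
  d <- generate_cohort(hunt_config(n_per_wave = 2000, seed = 71,
                                   missingness_rate = 0))
  spec <- mediation_spec("ht_high", mediators = "ear_infections")
  sc <- sensitivity_rho(d, spec)
  i0 <- which(sc$rho_grid == 0)
  expect_equal(sc$nie_at_rho[i0], sc$nie_rho0, tolerance = 1e-8)
  expect_equal(sc$nie_rho0, sc$alpha * sc$beta, tolerance = 1e-12)
  jumps <- abs(diff(sc$nie_at_rho))
  expect_lt(max(jumps), 5 * stats::median(jumps) + 1e-12)
  # true mediation in the generator: the NIE is nonzero at rho = 0 and is
  # explained away only at a nonzero residual correlation
  expect_gt(abs(sc$nie_rho0), 0)
  expect_false(isTRUE(all.equal(sc$rho_zero, 0)))
})

test_that("rho_zero recovers the closed-form residual correlation induced
          by an unmeasured mediator-outcome confounder", {
  # no true mediation: M and Y share the unmeasured U only
  set.seed(72)
  n <- 100000
  a <- 1; b <- 1.5; s_em <- 1; s_ey <- 2
  x <- rbinom(n, 1, 0.5)
  age <- runif(n, 20, 100)
  sex <- rbinom(n, 1, 0.5)
  U <- rnorm(n)
  m <- 0.3 * x + a * U + rnorm(n, sd = s_em)
  y <- -1 * x + 0.02 * age + b * U + rnorm(n, sd = s_ey)
  d <- data.frame(wave = x, age = age, sex = sex, m = m, ht_low = y)
  sd_m <- sqrt(a^2 + s_em^2)
  sd_y <- sqrt(b^2 + s_ey^2)
  rho_star <- a * b / (sd_m * sd_y)
  spec <- mediation_spec("ht_low", mediators = "m")
  sc <- sensitivity_rho(d, spec, rho_grid = seq(-0.6, 0.6, 0.01))
  expect_lt(abs(sc$rho_zero - rho_star), 0.02)
})

test_that("grid validation and non-crossing warning", {
  d <- generate_cohort(hunt_config(n_per_wave = 500, seed = 73,
                                   missingness_rate = 0))
  spec <- mediation_spec("ht_low", mediators = "smoking")
  expect_error(sensitivity_rho(d, spec, rho_grid = c(-1, 0, 1)), "< 1")
  expect_error(sensitivity_rho(d, spec, rho_grid = c(0.2, 0.1)), "increase")
  expect_warning(sensitivity_rho(d, spec,
                                 rho_grid = seq(-0.02, -0.01, 0.005)),
                 "cross")
  spec2 <- mediation_spec("ht_low", mediators = c("smoking", "noise"))
  expect_error(sensitivity_rho(d, spec2), "single")
})
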