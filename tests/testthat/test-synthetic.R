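test_that("identical config and seed give bit-identical cohorts", {
  cfg <- hunt_config(n_per_wave = 400, seed = 11)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  expect_false(identical(generate_cohort(cfg, seed = 12),
                         generate_cohort(cfg, seed = 13)))
})

test_that("configuration errors name the offending field", {
  cfg <- hunt_config(n_per_wave = 100)
  bad <- cfg; bad$mediator_models$smoking$baseline[2, 1, 1] <- 0.9
  expect_error(generate_cohort(bad), "smoking baseline")
  bad <- cfg; bad$outcome_models$ht_low$residual_sd <- -1
  expect_error(generate_cohort(bad), "residual_sd")
  bad <- cfg; bad$n_per_wave <- 0
  expect_error(generate_cohort(bad), "n_per_wave")
  bad <- cfg; bad$outcome_models$ht_high$noise <- c(0, 1, Inf, 2)
  expect_error(generate_cohort(bad), "noise")
})

test_that("large samples reproduce the configured marginals", {
  cfg <- hunt_config(n_per_wave = 100000, seed = 5, missingness_rate = 0)
  d <- generate_cohort(cfg)
  tol <- function(p, n) 3 * sqrt(p * (1 - p) / n)
  # current smoking among second-wave women: configured 9%
  w4w <- d[d$wave == 1 & d$sex == 0, ]
  p_hat <- mean(w4w$smoking == 3)
  expect_gt(p_hat, 0.09 - tol(0.09, nrow(w4w)))
  expect_lt(p_hat, 0.09 + tol(0.09, nrow(w4w)))
  expect_true(p_hat > 0.087 && p_hat < 0.093)
  # heavy occupational noise among first-wave men: configured 25/99
  h2m <- d[d$wave == 0 & d$sex == 1, ]
  p_cfg <- 25 / 99
  expect_lt(abs(mean(h2m$noise == 4) - p_cfg), tol(p_cfg, nrow(h2m)))
  # age bounds and location
  expect_true(all(d$age >= 20 & d$age <= 101))
  # truncation to [20, 101] lifts the location slightly above the nominal mean
  m0 <- mean(d$age[d$wave == 0]); m1 <- mean(d$age[d$wave == 1])
  expect_true(m0 > 48 && m0 < 54 && m1 > m0 && m1 < 57)
  expect_lt(abs(sd(d$age[d$wave == 0]) - 16.9), 1.5)
  expect_lt(abs(mean(d$sex[d$wave == 1] == 0) - 0.56), tol(0.56, 100000))
})

test_that("missingness hits mediators only, at the configured rate", {
  d <- generate_cohort(hunt_config(n_per_wave = 20000, seed = 2,
                                   missingness_rate = 0.09))
  meds <- c("noise", "ear_infections", "smoking")
  frac <- mean(!complete.cases(d[meds]))
  expect_lt(abs(frac - 0.09), 3 * sqrt(0.09 * 0.91 / nrow(d)))
  expect_false(anyNA(d[c("wave", "age", "sex", "education",
                         "ht_low", "ht_high")]))
})

test_that("threshold averaging follows the two frequency bands", {
  flat <- c("0.5" = 10, "1" = 10, "2" = 10, "3" = 10, "4" = 10, "6" = 10)
  expect_equal(unname(average_ht(flat, flat)), c(10, 10))
  left <- c("0.5" = 0, "1" = 0, "2" = 0, "3" = 10, "4" = 20, "6" = 30)
  right <- c("0.5" = 6, "1" = 6, "2" = 6, "3" = 10, "4" = 20, "6" = 30)
  got <- average_ht(left, right)
  expect_equal(unname(got["ht_low"]), 3)
  expect_equal(unname(got["ht_high"]), 20)
  expect_error(average_ht(left[-1], right), "0.5")
})

test_that("true effects: null config is exactly null and the
          decomposition telescopes", {
  te0 <- true_effects(null_config(10), "ht_low")
  expect_equal(te0$total, 0, tolerance = 1e-12)
  expect_equal(te0$nde, 0, tolerance = 1e-12)
  expect_equal(te0$nie_joint, 0, tolerance = 1e-12)
  expect_true(all(abs(te0$nie_by_mediator) < 1e-12))
  te <- true_effects(hunt_config(n_per_wave = 10), "ht_high")
  expect_equal(te$nde + te$nie_joint, te$total, tolerance = 1e-12)
  # single-mediator closed form: NIE = (p1 - p0) * b_m
  tl <- true_effects(toy_linear_config(10), "ht_low")
  expect_equal(tl$nie_joint, (0.5 - 0.3) * 2.0, tolerance = 1e-10)
  expect_equal(tl$total, -1.0 + 0.4, tolerance = 1e-10)
})

test_that("independent additive mediators: joint NIE is the sum of the
          specific NIEs, and matches a Monte Carlo oracle", {
  cfg <- toy_two_mediator_config(10)
  te <- true_effects(cfg, "ht_low")
  expect_equal(te$nie_joint,
               sum(te$nie_by_mediator[c("smoking", "noise")]),
               tolerance = 1e-10)
  expect_equal(unname(te$nie_by_mediator["education"]), 0, tolerance = 1e-12)
  # MC oracle: draw mediators from the configured cell probabilities under
  # each wave law and average the outcome means at x_direct = 1
  set.seed(42)
  R <- 400000
  mean_y <- function(mw) {      # mw: wave law generating the mediators
    smoking <- rbinom(R, 1, cfg$mediator_models$smoking$baseline[mw, 1, 2])
    noise <- rbinom(R, 1, cfg$mediator_models$noise$baseline[mw, 1, 2])
    mean(-1 + 2 * smoking - 1.5 * noise)
  }
  mc_nie <- mean_y(2) - mean_y(1)
  expect_lt(abs(mc_nie - te$nie_joint), 3 * sqrt(2 * 0.25 * 6.25 / R))
})

test_that("cohort round-trips through CSV with its sidecar schema", {
  d <- generate_cohort(hunt_config(n_per_wave = 50, seed = 3))
  tmp <- tempfile(fileext = ".csv")
  write_cohort(d, tmp)
  expect_true(file.exists(paste0(tmp, ".schema.json")))
  d2 <- read_cohort(tmp)
  expect_equal(d2$ht_low, d$ht_low, tolerance = 1e-12)
  expect_identical(d2$smoking, d$smoking)
  unlink(c(tmp, paste0(tmp, ".schema.json")))
})

test_that("generator config round-trips through YAML", {
  cfg <- toy_L_config(100, seed = 9)
  nested <- function(a) lapply(1:2, function(w) lapply(1:2, function(s)
    as.numeric(a[w, s, ])))
  raw <- unclass(cfg)
  raw$education_probs <- nested(cfg$education_probs)
  raw$mediator_models$smoking$baseline <-
    nested(cfg$mediator_models$smoking$baseline)
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(raw, tmp)
  cfg2 <- read_generator_config(tmp)
  expect_identical(generate_cohort(cfg2), generate_cohort(cfg))
  unlink(tmp)
})
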