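test_that("without an intermediate confounder, G-computation agrees with
          the natural effect model", {
  cfg <- toy_linear_config(10000, seed = 61)
  d <- generate_cohort(cfg)
  spec <- mediation_spec("ht_low", mediators = "smoking")
  ne <- estimate_joint_nie(d, spec, bootstrap = 80, seed = 1)
  gf <- gformula_specific_nie(d, spec,
                              gformula_config(mc_replicates = 20000, seed = 2))
  tol <- 3 * sqrt(ne$se["nie"]^2 + gf$mc_error^2)
  expect_lt(abs(gf$nie - ne$nie), tol)
  expect_lt(abs(gf$total_effect - ne$total_effect), 4 * ne$se["total"])
})

test_that("specific NIE through a mediator under an intermediate
          confounder recovers the path-tracing truth", {
  cfg <- toy_L_config(6000, seed = 62)
  truth <- true_effects(cfg, "ht_low")
  # closed form: (p1 - p0) * b_m = 0.3 * -2
  expect_equal(unname(truth$nie_by_mediator["smoking"]), -0.6,
               tolerance = 1e-10)
  d <- generate_cohort(cfg)
  for (ident in c("linear_L_effect", "no_XM_interaction")) {
    spec <- mediation_spec("ht_low", mediators = "smoking",
                           intermediate_confounder = "education",
                           identification = ident)
    gf <- gformula_specific_nie(
      d, spec, gformula_config(mc_replicates = 20000, seed = 3),
      bootstrap = 30, seed = 4)
    expect_lt(abs(gf$nie - (-0.6)), 3 * gf$se["nie"])
  }
})

test_that("the two identification strategies agree when the generator
          satisfies both assumptions", {
  diffs <- sapply(1:6, function(s) {
    d <- generate_cohort(toy_L_config(3000, edu_on_m = 0.3, seed = 200 + s))
    est <- sapply(c("no_XM_interaction", "linear_L_effect"), function(ident) {
      spec <- mediation_spec("ht_low", mediators = "smoking",
                             intermediate_confounder = "education",
                             identification = ident)
      gformula_specific_nie(d, spec,
        gformula_config(mc_replicates = 8000, seed = 5))$nie
    })
    est[1] - est[2]
  })
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)) + 0.02)
})

test_that("G-computation is bit-reproducible for a fixed seed and demands
          an identification strategy when a confounder is present", {
  d <- generate_cohort(toy_L_config(2000, seed = 63))
  spec <- mediation_spec("ht_low", mediators = "smoking",
                         intermediate_confounder = "education",
                         identification = "linear_L_effect")
  cfg <- gformula_config(mc_replicates = 3000, seed = 9)
  r1 <- gformula_specific_nie(d, spec, cfg)
  r2 <- gformula_specific_nie(d, spec, cfg)
  expect_identical(r1$nie, r2$nie)
  expect_identical(r1$total_effect, r2$total_effect)
  spec_bad <- mediation_spec("ht_low", mediators = "smoking",
                             intermediate_confounder = "education")
  expect_error(gformula_specific_nie(d, spec_bad, cfg), "identification")
  expect_warning(gformula_config(mc_replicates = 10) |>
                   (\(cc) gformula_specific_nie(d, spec, cc))(), "small")
})

test_that("partial education effect recovers the truth and ignores an
          irrelevant control mediator", {
  # education -> Y linear (-1 per level), E[score] shift +0.5 across waves,
  # education has no effect on the control mediator
  cfg <- generator_config(
    n_per_wave = 6000,
    age = list(mean = c(50, 50), sd = c(15, 15), min = 20, max = 101),
    p_female = c(0.5, 0.5),
    education_probs = cells(c(0.40, 0.35, 0.15, 0.10),
                            c(0.20, 0.35, 0.25, 0.20)),
    mediator_models = list(
      noise = list(levels = 2, baseline = cells(c(0.6, 0.4), c(0.5, 0.5))),
      smoking = list(levels = 2, baseline = cells(c(0.7, 0.3), c(0.6, 0.4)))),
    outcome_models = list(
      ht_low = list(intercept = 1, wave = -0.8, sex_male = 0.4, age = c(1, 0),
                    education = -1 * c(0, 1, 2, 3),
                    noise = c(0, 1), smoking = c(0, 0.5), residual_sd = 2)),
    seed = 64)
  p <- cfg$education_probs
  truth_shift <- sum((1:4) * p[2, 1, ]) - sum((1:4) * p[1, 1, ])
  expect_equal(truth_shift, 0.5, tolerance = 1e-12)
  te <- true_effects(cfg, "ht_low")
  expect_equal(unname(te$nie_by_mediator["education"]), -0.5,
               tolerance = 1e-10)
  d <- generate_cohort(cfg)
  spec <- mediation_spec("ht_low", mediators = "education")
  gn <- partial_nie_education(d, spec, control = "noise",
                              config = gformula_config(8000, seed = 6),
                              bootstrap = 30, seed = 7)
  expect_lt(abs(gn$nie - (-0.5)), 3 * gn$se["nie"])
  gs <- partial_nie_education(d, spec, control = "smoking",
                              config = gformula_config(8000, seed = 6))
  expect_lt(abs(gn$nie - gs$nie), 3 * gn$se["nie"])
  expect_identical(gs$tag, "partial")
  expect_error(partial_nie_education(d, spec, control = "nope"), "absent")
})

test_that("assumption tests keep their size under the null and detect a
          strong exposure-mediator interaction", {
  spec <- mediation_spec("ht_low",
                         mediators = c("ear_infections", "noise", "smoking"),
                         intermediate_confounder = "education")
  rej <- sapply(1:30, function(s) {
    d <- generate_cohort(hunt_config(n_per_wave = 750, seed = 300 + s,
                                     missingness_rate = 0))
    rep <- test_identification_assumptions(d, spec)
    rep$tests$p_value[rep$tests$term == "XM_joint"] < 0.05
  })
  expect_lt(mean(rej), 0.2)     # near the nominal 5% level
  # power: 1.5 dB wave-by-noise interaction
  cfgx <- hunt_config(n_per_wave = 10000, missingness_rate = 0, seed = 65)
  cfgx$outcome_models$ht_low$wave_x <- list(noise = c(0, 1.5, 1.5, 1.5))
  dx <- generate_cohort(cfgx)
  repx <- test_identification_assumptions(dx, spec)
  expect_lt(repx$tests$p_value[repx$tests$term == "XM_noise"], 1e-3)
  expect_lt(repx$tests$p_value[repx$tests$term == "XM_joint"], 1e-3)
  expect_true(all(c("XM_joint", "XL", "L_nonlinearity") %in% repx$tests$term))
  expect_true(repx$recommended %in% c("no_XM_interaction", "linear_L_effect"))
})
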