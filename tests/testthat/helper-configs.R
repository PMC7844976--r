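# Toy generator configurations with closed-form truths, built in code.

# same cell probabilities for both sexes
cells <- function(w0, w1) prob_array(w0, w0, w1, w1)

flat_edu <- cells(c(0.4, 0.3, 0.2, 0.1), c(0.4, 0.3, 0.2, 0.1))

# single binary mediator ("smoking", levels 1/2) whose prevalence moves
# from p0 to p1 across waves; Y = intercept + b_wave * wave + b_m * 1{M=2}.
# True NIE = (p1 - p0) * b_m; no education or interaction paths.
toy_linear_config <- function(n_per_wave, p0 = 0.3, p1 = 0.5,
                              b_wave = -1.0, b_m = 2.0, residual_sd = 2,
                              wave_x_m = NULL, seed = 1L) {
  generator_config(
    n_per_wave = n_per_wave,
    age = list(mean = c(50, 50), sd = c(15, 15), min = 20, max = 101),
    p_female = c(0.5, 0.5),
    education_probs = flat_edu,
    mediator_models = list(
      smoking = list(levels = 2,
                     baseline = cells(c(1 - p0, p0), c(1 - p1, p1)))),
    outcome_models = list(
      ht_low = list(intercept = 3, wave = b_wave, sex_male = 0.5,
                    age = c(1, 0), education = c(0, 0, 0, 0),
                    smoking = c(0, b_m),
                    wave_x = if (is.null(wave_x_m)) NULL
                             else list(smoking = c(0, wave_x_m)),
                    residual_sd = residual_sd)),
    seed = seed)
}

# two independent binary mediators with additive outcome effects
toy_two_mediator_config <- function(n_per_wave, seed = 1L) {
  generator_config(
    n_per_wave = n_per_wave,
    age = list(mean = c(50, 50), sd = c(15, 15), min = 20, max = 101),
    p_female = c(0.5, 0.5),
    education_probs = flat_edu,
    mediator_models = list(
      smoking = list(levels = 2, baseline = cells(c(0.7, 0.3), c(0.5, 0.5))),
      noise = list(levels = 2, baseline = cells(c(0.4, 0.6), c(0.6, 0.4)))),
    outcome_models = list(
      ht_low = list(intercept = 0, wave = -1, sex_male = 0, age = c(0.5, 0),
                    education = c(0, 0, 0, 0),
                    smoking = c(0, 2), noise = c(0, -1.5),
                    residual_sd = 2)),
    seed = seed)
}

# exposure-induced intermediate confounder structure:
# wave shifts education (linear score effect on Y), a binary mediator
# depends on wave (and optionally education), Y linear in everything.
# With edu_on_m = 0: true specific NIE through smoking = (p1 - p0) * b_m.
toy_L_config <- function(n_per_wave, p0 = 0.4, p1 = 0.7, b_m = -2.0,
                         b_L = 1.0, edu_on_m = 0, seed = 1L) {
  generator_config(
    n_per_wave = n_per_wave,
    age = list(mean = c(50, 50), sd = c(15, 15), min = 20, max = 101),
    p_female = c(0.5, 0.5),
    # E[score] rises by 0.4 between waves
    education_probs = cells(c(0.40, 0.35, 0.15, 0.10),
                            c(0.25, 0.30, 0.25, 0.20)),
    mediator_models = list(
      smoking = list(levels = 2,
                     baseline = cells(c(1 - p0, p0), c(1 - p1, p1)),
                     edu_coef = edu_on_m)),
    outcome_models = list(
      ht_low = list(intercept = 2, wave = -0.5, sex_male = 0.3,
                    age = c(1, 0),
                    education = b_L * c(0, 1, 2, 3),
                    smoking = c(0, b_m),
                    residual_sd = 2)),
    seed = seed)
}

# no wave effect anywhere: all true effects are zero
null_config <- function(n_per_wave, seed = 1L) {
  cfg <- hunt_config(n_per_wave = n_per_wave, seed = seed,
                     missingness_rate = 0)
  cfg$age$mean <- c(50, 50)
  cfg$p_female <- c(0.5, 0.5)
  for (s in 1:2) cfg$education_probs[2, s, ] <- cfg$education_probs[1, s, ]
  for (m in names(cfg$mediator_models)) for (s in 1:2)
    cfg$mediator_models[[m]]$baseline[2, s, ] <-
      cfg$mediator_models[[m]]$baseline[1, s, ]
  for (y in names(cfg$outcome_models)) cfg$outcome_models[[y]]$wave <- 0
  cfg
}

joint_spec_for <- function(cfg, outcome = "ht_low", ...) {
  mediation_spec(outcome, mediators = names(cfg$mediator_models), ...)
}
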