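#' Build a synthetic-cohort generator configuration
#'
#' The generator draws two cross-sectional waves.  Within each wave, age is
#' truncated-normal, sex is Bernoulli, education is categorical per
#' (wave, sex), and each mediator follows a categorical-logit model whose
#' baseline (per wave and sex) cell probabilities can be shifted on the
#' logit scale by centred education score and centred age.  The two hearing
#' outcomes are linear in wave, sex, a smooth (linear + quadratic) age
#' trend, education level and mediator level, with optional wave-by-mediator
#' and wave-by-education interactions and Gaussian residual noise.
#'
#' @param n_per_wave subjects per wave (>= 1).
#' @param age list with \code{mean} and \code{sd} (length-2, one per wave)
#'   and truncation bounds \code{min}, \code{max} in years.
#' @param p_female length-2 probability of female sex per wave.
#' @param education_probs numeric array \code{[wave, sex, 4]} of education
#'   probabilities (sex index 1 = female, 2 = male); rows sum to 1.
#' @param mediator_models named list; each element has \code{levels} (K),
#'   \code{baseline} (array \code{[wave, sex, K]} of cell probabilities),
#'   and optional \code{edu_coef}, \code{age_coef} (length K - 1 logit
#'   shifts per non-reference level, on centred education score and on
#'   centred age in decades).
#' @param outcome_models named list of linear outcome models; each element
#'   has \code{intercept}, \code{wave}, \code{sex_male}, \code{age}
#'   (length-2: dB per decade linear and quadratic, centred at 50 y),
#'   \code{education} (length-4, first entry 0), one length-K coefficient
#'   vector per mediator (first entry 0), \code{residual_sd} (dB), and
#'   optional \code{wave_x} (named list of wave-by-mediator interaction
#'   vectors) and \code{wave_x_education}.
#' @param missingness_rate probability that a subject is missing at least
#'   one mediator (missing-completely-at-random; one of the subject's
#'   mediators, chosen uniformly, is blanked).  Education is never blanked.
#' @param seed integer default seed for [generate_cohort()].
#' @return validated object of class \code{"generator_config"}.
#' @seealso [hunt_config()] for defaults emulating the two study waves.
#' @export
generator_config <- function(n_per_wave,
                             age = list(mean = c(50, 50), sd = c(16.9, 16.9),
                                        min = 20, max = 101),
                             p_female = c(0.5, 0.5),
                             education_probs,
                             mediator_models,
                             outcome_models,
                             missingness_rate = 0,
                             seed = 1L) {
  cfg <- structure(list(n_per_wave = n_per_wave, age = age,
                        p_female = p_female,
                        education_probs = education_probs,
                        mediator_models = mediator_models,
                        outcome_models = outcome_models,
                        missingness_rate = missingness_rate,
                        seed = as.integer(seed)),
                   class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' @param cfg a \code{generator_config} (or a plain list with the same
#'   fields, e.g. read from YAML).
#' @return \code{cfg}, invisibly, or an error naming the offending field.
#' @export
validate_generator_config <- function(cfg) {
  stop_field <- function(field, msg) stop("generator config, field '", field,
                                          "': ", msg, call. = FALSE)
  if (!is.numeric(cfg$n_per_wave) || length(cfg$n_per_wave) != 1 ||
      is.na(cfg$n_per_wave) || cfg$n_per_wave < 1)
    stop_field("n_per_wave", "must be a positive integer")
  a <- cfg$age
  if (length(a$mean) != 2 || length(a$sd) != 2 || any(a$sd <= 0))
    stop_field("age", "needs per-wave mean and positive sd")
  if (a$min >= a$max) stop_field("age", "min must be below max")
  if (length(cfg$p_female) != 2 || any(cfg$p_female < 0 | cfg$p_female > 1))
    stop_field("p_female", "two probabilities in [0, 1]")
  check_probs <- function(p, field) {
    if (any(p < 0) || any(!is.finite(p))) stop_field(field, "negative or non-finite probability")
    if (abs(sum(p) - 1) > 1e-12)
      stop_field(field, sprintf("probabilities sum to %.15f, not 1", sum(p)))
  }
  ep <- cfg$education_probs
  if (!is.array(ep) || !all(dim(ep) == c(2, 2, 4)))
    stop_field("education_probs", "must be a [2 wave, 2 sex, 4 level] array")
  for (w in 1:2) for (s in 1:2)
    check_probs(ep[w, s, ], sprintf("education_probs[wave %d, sex %d]", w, s))
  if (is.null(names(cfg$mediator_models)) || length(cfg$mediator_models) < 1)
    stop_field("mediator_models", "must be a non-empty named list")
  for (m in names(cfg$mediator_models)) {
    mm <- cfg$mediator_models[[m]]
    K <- mm$levels
    if (is.null(K) || K < 2) stop_field(m, "mediator needs >= 2 levels")
    if (!is.array(mm$baseline) || !all(dim(mm$baseline) == c(2, 2, K)))
      stop_field(m, sprintf("baseline must be a [2, 2, %d] array", K))
    for (w in 1:2) for (s in 1:2)
      check_probs(mm$baseline[w, s, ], sprintf("%s baseline[wave %d, sex %d]", m, w, s))
    for (cf in c("edu_coef", "age_coef")) {
      v <- mm[[cf]]
      if (!is.null(v) && (length(v) != K - 1 || any(!is.finite(v))))
        stop_field(m, paste0(cf, " must be finite, length levels - 1"))
    }
  }
  if (is.null(names(cfg$outcome_models)) || length(cfg$outcome_models) < 1)
    stop_field("outcome_models", "must be a non-empty named list")
  for (y in names(cfg$outcome_models)) {
    om <- cfg$outcome_models[[y]]
    scalars <- c(om$intercept, om$wave, om$sex_male, om$age, om$education)
    if (any(!is.finite(scalars)))
      stop_field(y, "non-finite coefficient")
    if (length(om$education) != 4 || om$education[1] != 0)
      stop_field(y, "education coefficients: length 4, reference (first) 0")
    for (m in names(cfg$mediator_models)) {
      K <- cfg$mediator_models[[m]]$levels
      v <- om[[m]]
      if (is.null(v) || length(v) != K || v[1] != 0 || any(!is.finite(v)))
        stop_field(y, sprintf("'%s' coefficients: finite, length %d, reference 0", m, K))
      w <- om$wave_x[[m]]
      if (!is.null(w) && (length(w) != K || any(!is.finite(w))))
        stop_field(y, sprintf("wave_x$%s: finite, length %d", m, K))
    }
    if (!is.null(om$wave_x_education) &&
        (length(om$wave_x_education) != 4 || any(!is.finite(om$wave_x_education))))
      stop_field(y, "wave_x_education: finite, length 4")
    if (!is.numeric(om$residual_sd) || om$residual_sd <= 0)
      stop_field(y, "residual_sd must be > 0")
  }
  if (cfg$missingness_rate < 0 || cfg$missingness_rate >= 1)
    stop_field("missingness_rate", "must be in [0, 1)")
  invisible(cfg)
}

# probability array [wave, sex, level] from four per-cell vectors,
# normalised to sum exactly to 1
prob_array <- function(w0_f, w0_m, w1_f, w1_m) {
  K <- length(w0_f)
  out <- array(0, c(2, 2, K))
  out[1, 1, ] <- w0_f / sum(w0_f)
  out[1, 2, ] <- w0_m / sum(w0_m)
  out[2, 1, ] <- w1_f / sum(w1_f)
  out[2, 2, ] <- w1_m / sum(w1_m)
  out
}

#' Default configuration emulating the two hearing-study waves
#'
#' Marginal distributions of education, recurrent ear infections,
#' occupational noise exposure and daily smoking per wave and sex follow
#' the published risk-factor distributions of the two waves (1996-1998 and
#' 2017-2019), as do the age distributions (mean about 50 and 53 years,
#' SD 16.9, range 20-101) and the proportions of women (53\% and 56\%).
#' Outcome-model coefficients are illustrative (plausible dB effects with
#' the harmful-exposure levels raising thresholds and higher education
#' lowering them); the real study does not publish its fitted
#' coefficients.  Secular change in the mediator distributions between the
#' waves is what generates the true indirect effects.
#'
#' @param n_per_wave subjects per wave.
#' @param seed default generator seed.
#' @param missingness_rate probability a subject lacks at least one
#'   mediator (default 0.09, the study's complete-case loss).
#' @return a \code{generator_config}.
#' @examples
#' cfg <- hunt_config(n_per_wave = 500)
#' d <- generate_cohort(cfg)
#' table(d$wave)
#' @export
hunt_config <- function(n_per_wave = 20000, seed = 1L,
                        missingness_rate = 0.09) {
  generator_config(
    n_per_wave = n_per_wave,
    age = list(mean = c(50.1, 53.2), sd = c(16.9, 16.9), min = 20, max = 101),
    p_female = c(0.53, 0.56),
    education_probs = prob_array(c(32, 48, 18, 1), c(26, 56, 13, 5),
                                 c(13, 43, 37, 6), c(12, 56, 22, 9)),
    mediator_models = list(
      ear_infections = list(levels = 3,
        baseline = prob_array(c(72, 5, 23), c(77, 6, 17),
                              c(80, 3, 17), c(85, 2, 13))),
      noise = list(levels = 4,
        baseline = prob_array(c(79, 10, 5, 6), c(36, 22, 16, 25),
                              c(86, 4, 6, 4), c(58, 12, 16, 15))),
      smoking = list(levels = 3,
        baseline = prob_array(c(48, 23, 29), c(39, 34, 27),
                              c(56, 35, 9), c(56, 38, 6)))),
    outcome_models = list(
      ht_low = list(intercept = 5, wave = -2.0, sex_male = 1.0,
                    age = c(4.5, 1.8),
                    education = c(0, -0.6, -1.0, -1.4),
                    ear_infections = c(0, 1.0, 2.2),
                    noise = c(0, 0.6, 1.2, 2.0),
                    smoking = c(0, 0.6, 1.6),
                    residual_sd = 7.5),
      ht_high = list(intercept = 10, wave = -2.2, sex_male = 6.0,
                     age = c(7.0, 2.5),
                     education = c(0, -0.5, -0.9, -1.3),
                     ear_infections = c(0, 1.2, 2.6),
                     noise = c(0, 1.0, 2.2, 3.5),
                     smoking = c(0, 0.8, 2.0),
                     residual_sd = 9.5)),
    missingness_rate = missingness_rate,
    seed = seed)
}

#' Read a generator configuration from YAML or JSON
#'
#' The file holds the same fields as [generator_config()]; probability
#' arrays are given as nested lists \code{[wave][sex][level]}.
#'
#' @param path file path ending in .yaml/.yml or .json.
#' @return a validated \code{generator_config}.
#' @export
read_generator_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  to_array <- function(x, K) {
    out <- array(0, c(2, 2, K))
    for (w in 1:2) for (s in 1:2) out[w, s, ] <- as.numeric(x[[w]][[s]])
    out
  }
  raw$education_probs <- to_array(raw$education_probs, 4)
  for (m in names(raw$mediator_models)) {
    K <- raw$mediator_models[[m]]$levels
    raw$mediator_models[[m]]$baseline <-
      to_array(raw$mediator_models[[m]]$baseline, K)
  }
  for (y in names(raw$outcome_models)) {
    om <- raw$outcome_models[[y]]
    raw$outcome_models[[y]] <- lapply(om, function(v)
      if (is.list(v)) lapply(v, as.numeric) else as.numeric(v))
  }
  do.call(generator_config, raw[c("n_per_wave", "age", "p_female",
                                  "education_probs", "mediator_models",
                                  "outcome_models", "missingness_rate",
                                  "seed")])
}
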