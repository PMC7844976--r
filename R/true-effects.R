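# Population truth for a generator configuration, by exact enumeration.
#
# The target population is the pooled covariate distribution of a balanced
# two-wave sample: an equal mixture of the two waves' (age, sex) laws.
# Counterfactual regimes fix (i) the exposure level entering the outcome
# model directly (and its interaction terms), (ii) the wave law generating
# education, and (iii) per mediator, the wave law generating that mediator
# and which education draw it conditions on ("y" = the same draw the
# outcome sees, "alt" = an independent cross-world draw from another wave's
# law).  Because the outcome is linear in category indicators, expectations
# over mediator categories are sums over level probabilities, so every
# regime mean is computed exactly (age integrals by Simpson quadrature).

# Simpson weights over the truncated-normal age law of covariate-wave w
age_quadrature <- function(config, w, n_nodes = 201) {
  lo <- config$age$min; hi <- config$age$max
  x <- seq(lo, hi, length.out = n_nodes)
  dens <- stats::dnorm(x, config$age$mean[w], config$age$sd[w])
  h <- (hi - lo) / (n_nodes - 1)
  sw <- c(1, rep(c(4, 2), length.out = n_nodes - 2), 1)
  sw[n_nodes - 1] <- 4
  wts <- dens * sw * h / 3
  wts <- wts / sum(wts)
  list(age = x, w = wts)
}

# K-vector of mediator-level probabilities for one (wave law, sex, edu)
# cell, at a vector of ages; returns length(age) x K matrix
mediator_prob_matrix <- function(mm, wl, sex, edu, age) {
  K <- mm$levels
  base <- mm$baseline[wl, sex + 1L, ]
  eta <- matrix(log(base[-1] / base[1]), length(age), K - 1, byrow = TRUE)
  if (!is.null(mm$edu_coef))
    eta <- eta + matrix(mm$edu_coef * (edu - 2.5), length(age), K - 1,
                        byrow = TRUE)
  if (!is.null(mm$age_coef))
    eta <- eta + outer((age - 50) / 10, mm$age_coef)
  expo <- cbind(1, exp(eta))
  expo / rowSums(expo)
}

# exact mean of one outcome under a counterfactual regime
regime_mean <- function(config, outcome, x_d, xl_y,
                        med_x, med_l = NULL, xl_alt = xl_y) {
  om <- config$outcome_models[[outcome]]
  meds <- names(config$mediator_models)
  if (is.null(med_l)) med_l <- stats::setNames(rep("y", length(meds)), meds)
  total <- 0
  for (wc in 1:2) {                       # covariate-wave mixture component
    quad <- age_quadrature(config, wc)
    age_c <- (quad$age - 50) / 10
    for (sex in 0:1) {
      p_sex <- if (sex == 0) config$p_female[wc] else 1 - config$p_female[wc]
      if (p_sex == 0) next
      for (l_y in 1:4) {
        p_ly <- config$education_probs[xl_y + 1L, sex + 1L, l_y]
        if (p_ly == 0) next
        # outcome terms that depend only on (sex, l_y, age)
        mu <- om$intercept + om$wave * x_d + om$sex_male * sex +
          om$age[1] * age_c + om$age[2] * age_c^2 +
          om$education[l_y] +
          (if (!is.null(om$wave_x_education)) x_d * om$wave_x_education[l_y] else 0)
        # mediators conditioning on the outcome-world education draw
        for (m in meds[med_l[meds] == "y"]) {
          pm <- mediator_prob_matrix(config$mediator_models[[m]],
                                     med_x[[m]] + 1L, sex, l_y, quad$age)
          coefs <- om[[m]] +
            (if (!is.null(om$wave_x[[m]])) x_d * om$wave_x[[m]] else 0)
          mu <- mu + as.vector(pm %*% coefs)
        }
        # mediators conditioning on an independent cross-world draw
        alt <- meds[med_l[meds] == "alt"]
        if (length(alt)) {
          for (m in alt) {
            coefs <- om[[m]] +
              (if (!is.null(om$wave_x[[m]])) x_d * om$wave_x[[m]] else 0)
            emu <- 0
            for (l_a in 1:4) {
              p_la <- config$education_probs[xl_alt + 1L, sex + 1L, l_a]
              if (p_la == 0) next
              pm <- mediator_prob_matrix(config$mediator_models[[m]],
                                         med_x[[m]] + 1L, sex, l_a, quad$age)
              emu <- emu + p_la * as.vector(pm %*% coefs)
            }
            mu <- mu + emu
          }
        }
        total <- total + 0.5 * p_sex * p_ly * sum(quad$w * mu)
      }
    }
  }
  total
}

#' True population effects implied by a generator configuration
#'
#' Computes the total effect, the natural direct effect, the joint natural
#' indirect effect, and mediator-specific natural indirect effects by exact
#' path enumeration over the configured categorical-logit mediator models
#' and linear outcome model (age integrals by quadrature; no Monte Carlo
#' error).  The education-specific effect is the partial natural indirect
#' effect, holding the co-mediators at their second-wave laws.
#'
#' @param config a [generator_config()].
#' @param outcome outcome name(s); default all configured outcomes.
#' @return for a single outcome, a list of class \code{"true_effects"} with
#'   \code{total}, \code{nde}, \code{nie_joint}, \code{nie_by_mediator}
#'   (named, including \code{education}) and \code{derivation} (the regime
#'   means); for several outcomes, a named list of such objects.
#' @examples
#' true_effects(hunt_config(n_per_wave = 10), outcome = "ht_low")$nie_joint
#' @export
true_effects <- function(config, outcome = names(config$outcome_models)) {
  validate_generator_config(config)
  if (length(outcome) > 1) {
    out <- lapply(outcome, function(y) true_effects(config, y))
    names(out) <- outcome
    return(out)
  }
  if (!outcome %in% names(config$outcome_models))
    stop("unknown outcome: ", outcome)
  meds <- names(config$mediator_models)
  all1 <- stats::setNames(rep(1, length(meds)), meds)
  all0 <- stats::setNames(rep(0, length(meds)), meds)
  ey11 <- regime_mean(config, outcome, x_d = 1, xl_y = 1, med_x = all1)
  ey00 <- regime_mean(config, outcome, x_d = 0, xl_y = 0, med_x = all0)
  ey10 <- regime_mean(config, outcome, x_d = 1, xl_y = 0, med_x = all0)
  total <- ey11 - ey00
  nde <- ey10 - ey00
  nie_joint <- ey11 - ey10
  nie <- numeric(0)
  for (m in meds) {
    mx <- all1; mx[m] <- 0
    ml <- stats::setNames(rep("y", length(meds)), meds); ml[m] <- "alt"
    arm <- regime_mean(config, outcome, x_d = 1, xl_y = 1,
                       med_x = mx, med_l = ml, xl_alt = 0)
    nie[m] <- ey11 - arm
  }
  # education: partial indirect effect, co-mediator laws fixed at wave 1
  ml_alt <- stats::setNames(rep("alt", length(meds)), meds)
  arm_edu <- regime_mean(config, outcome, x_d = 1, xl_y = 0,
                         med_x = all1, med_l = ml_alt, xl_alt = 1)
  nie["education"] <- ey11 - arm_edu
  structure(list(outcome = outcome, total = total, nde = nde,
                 nie_joint = nie_joint, nie_by_mediator = nie,
                 derivation = list(ey11 = ey11, ey00 = ey00, ey10 = ey10,
                                   method = "analytic path enumeration")),
            class = "true_effects")
}

#' @export
print.true_effects <- function(x, ...) {
  cat("True effects (", x$outcome, "), dB:\n", sep = "")
  cat(sprintf("  total %8.4f   NDE %8.4f   joint NIE %8.4f\n",
              x$total, x$nde, x$nie_joint))
  for (m in names(x$nie_by_mediator))
    cat(sprintf("  NIE via %-15s %8.4f\n", m, x$nie_by_mediator[m]))
  invisible(x)
}
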