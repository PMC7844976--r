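# Mediator-specific natural indirect effects by parametric G-computation
# with Monte Carlo simulation, under exposure-induced intermediate
# confounding (education), and the assumption-selection tests used to
# choose between the two identification strategies.

#' Settings for the G-computation estimator
#'
#' @param mc_replicates Monte Carlo sample size per counterfactual regime;
#'   \code{NULL} (default) uses \code{max(n, 100000)} at run time.  Values
#'   below 1000 trigger a warning for estimation runs.
#' @param identification optional override of the spec's identification
#'   strategy (\code{"no_XM_interaction"} or \code{"linear_L_effect"}).
#' @param seed integer seed for the Monte Carlo draws.
#' @return object of class \code{"gformula_config"}.
#' @export
gformula_config <- function(mc_replicates = NULL, identification = NULL,
                            seed = 1L) {
  if (!is.null(identification) &&
      !identification %in% c("no_XM_interaction", "linear_L_effect"))
    stop("identification must be 'no_XM_interaction' or 'linear_L_effect'")
  structure(list(mc_replicates = mc_replicates,
                 identification = identification, seed = as.integer(seed)),
            class = "gformula_config")
}

# shared machinery: draw the baseline-covariate sample and return a
# template data frame plus a setter for counterfactual columns
mc_covariates <- function(data, config) {
  R <- config$mc_replicates
  if (is.null(R)) R <- max(nrow(data), 100000L)
  if (R < 1000)
    warning("mc_replicates = ", R, " is small for estimation runs; ",
            "Monte Carlo error may dominate")
  set.seed(config$seed)
  idx <- sample.int(nrow(data), R, replace = TRUE)
  data[idx, , drop = FALSE]
}

#' Mediator-specific natural indirect effect by parametric G-computation
#'
#' Fits parametric models for the intermediate confounder (multinomial
#' logit given exposure and baseline covariates), the focal mediator
#' (multinomial logit given exposure, confounder and covariates) and the
#' outcome (linear model whose interaction structure follows the
#' identification strategy), then computes counterfactual means by Monte
#' Carlo over the empirical covariate distribution with exact enumeration
#' over confounder and mediator categories.  The specific natural indirect
#' effect contrasts E[Y(1, M(1))] with E[Y(1, M(0))], the mediator's
#' cross-world draw conditioning on its own confounder world; the total
#' effect contrasts the two all-of-one-wave regimes.
#'
#' Identification with an intermediate confounder requires one of two
#' extra parametric assumptions: \code{"no_XM_interaction"} omits the
#' exposure-mediator interaction from the outcome model (exposure-
#' confounder interaction permitted), while \code{"linear_L_effect"}
#' enters the confounder as a linear ordinal score with no exposure-
#' confounder interaction (exposure-mediator interaction permitted).
#' Use [test_identification_assumptions()] to choose.
#'
#' @param data cohort data, complete on model columns.
#' @param spec a [mediation_spec()] with exactly one mediator (the focal
#'   one) and, if needed, an intermediate confounder with an
#'   identification strategy.
#' @param config a [gformula_config()].
#' @param bootstrap bootstrap draws for standard errors (0 = none).
#' @param seed bootstrap seed.
#' @return a \code{"mediation_result"}; \code{nde} is reported as the
#'   remainder (total minus the specific NIE), and \code{mc_error} is the
#'   Monte Carlo standard error of the NIE contrast.
#' @examples
#' d <- generate_cohort(hunt_config(n_per_wave = 1500, missingness_rate = 0))
#' spec <- mediation_spec("ht_high", mediators = "noise",
#'                        intermediate_confounder = "education",
#'                        identification = "linear_L_effect")
#' gformula_specific_nie(d, spec, gformula_config(mc_replicates = 5000))
#' @export
gformula_specific_nie <- function(data, spec, config = gformula_config(),
                                  bootstrap = 0, seed = NULL) {
  if (length(spec$mediators) != 1)
    stop("gformula_specific_nie: spec must name exactly one focal mediator")
  data <- apply_stratum(data, spec)
  assert_complete(data, spec)
  assert_binary_exposure(data, spec)
  L <- spec$intermediate_confounder
  ident <- config$identification %||% spec$identification
  if (!is.null(L) && ident == "none_required")
    stop("an identification strategy (no_XM_interaction or linear_L_effect) ",
         "is required when an intermediate confounder is present")
  spec <- within_spec(spec, identification = ident)
  core <- function(d, mc_seed) {
    cfg <- config; cfg$seed <- mc_seed
    gformula_point(d, spec, cfg)
  }
  est <- core(data, config$seed)
  se <- ci <- NULL
  if (bootstrap > 0) {
    # fresh MC seeds per draw so the bootstrap SE includes MC noise
    bs <- bootstrap_ci(function(d)
      core(d, sample.int(.Machine$integer.max, 1))$estimates,
      data, n_draws = bootstrap, seed = seed)
    se <- bs$se; ci <- bs$ci_normal
  }
  mediation_result(est$estimates["total"],
                   est$estimates["total"] - est$estimates["nie"],
                   est$estimates["nie"],
                   method = "gformula", stratum = spec$stratum,
                   n_used = nrow(data), se = se, ci = ci,
                   mc_error = est$mc_error,
                   identification = if (is.null(L)) NULL else ident)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

within_spec <- function(spec, ...) {
  mod <- list(...)
  spec[names(mod)] <- mod
  spec
}

# point estimate: (total, nie) plus MC error, for a single focal mediator
gformula_point <- function(data, spec, config) {
  x_col <- spec$exposure
  med <- spec$mediators
  L <- spec$intermediate_confounder
  ident <- spec$identification
  covs <- spec$covariates
  # component models
  yfit <- switch(ident,
    no_XM_interaction = fit_outcome_model(data, spec, xm_interactions = FALSE,
                                          xl_interaction = TRUE),
    linear_L_effect = fit_outcome_model(data, spec, xm_interactions = TRUE,
                                        l_linear = TRUE),
    fit_outcome_model(data, spec))
  mfit <- fit_categorical_model(data, med,
                                predictors = c(x_col, L, covs),
                                age_knots = yfit$knots)
  lfit <- if (!is.null(L))
    fit_categorical_model(data, L, predictors = c(x_col, covs),
                          age_knots = yfit$knots)
  Cdf <- mc_covariates(data, config)
  R <- nrow(Cdf)
  at <- function(x, l = NULL, m = NULL) {
    nd <- Cdf
    nd[[x_col]] <- x
    if (!is.null(l)) nd[[L]] <- l
    if (!is.null(m)) nd[[med]] <- m
    nd
  }
  if (is.null(L)) {
    pm <- list(`0` = predict_probs(mfit, at(0)),
               `1` = predict_probs(mfit, at(1)))
    mlv <- mfit$levels
    ey <- function(x, pmx) {          # E[Y(x, M~pmx)] per covariate row
      out <- numeric(R)
      for (k in seq_along(mlv))
        out <- out + pmx[, k] * predict_ht(yfit, at(x, m = mlv[k]))
      out
    }
    ey11 <- ey(1, pm$`1`)
    ey10 <- ey(1, pm$`0`)
    ey00 <- ey(0, pm$`0`)
    nie_row <- ey11 - ey10
    tot_row <- ey11 - ey00
  } else {
    llv <- lfit$levels
    mlv <- mfit$levels
    pl <- list(`0` = predict_probs(lfit, at(0)),
               `1` = predict_probs(lfit, at(1)))
    # P(M = k | X = x, L = l, C), per (x, l)
    pm <- lapply(c(0, 1), function(x)
      lapply(llv, function(l) predict_probs(mfit, at(x, l = l))))
    names(pm) <- c("0", "1")
    # marginal mediator law under wave x, integrating its own L(x)
    pm_marg <- function(x) {
      out <- matrix(0, R, length(mlv))
      for (j in seq_along(llv))
        out <- out + pl[[as.character(x)]][, j] * pm[[as.character(x)]][[j]]
      out
    }
    ey_grid <- function(x) {          # E[Y | x, l, m, C] for all (l, m)
      g <- vector("list", length(llv))
      for (j in seq_along(llv)) {
        g[[j]] <- matrix(0, R, length(mlv))
        for (k in seq_along(mlv))
          g[[j]][, k] <- predict_ht(yfit, at(x, l = llv[j], m = mlv[k]))
      }
      g
    }
    g1 <- ey_grid(1)
    # consistent world at x: L(x) and M(x) share the L draw
    ey_cons <- function(x, g) {
      out <- numeric(R)
      for (j in seq_along(llv))
        out <- out +
          pl[[as.character(x)]][, j] *
          rowSums(pm[[as.character(x)]][[j]] * g[[j]])
      out
    }
    ey11 <- ey_cons(1, g1)
    # cross-world: Y and L at wave 1, mediator from its marginal wave-0 law
    pm0 <- pm_marg(0)
    ey10 <- numeric(R)
    for (j in seq_along(llv))
      ey10 <- ey10 + pl$`1`[, j] * rowSums(g1[[j]] * pm0)
    ey00 <- ey_cons(0, ey_grid(0))
    nie_row <- ey11 - ey10
    tot_row <- ey11 - ey00
  }
  list(estimates = c(total = mean(tot_row), nie = mean(nie_row)),
       mc_error = stats::sd(nie_row) / sqrt(R))
}

#' Partial natural indirect effect through education
#'
#' Education is both a mediator of interest and an intermediate confounder
#' of the behavioural mediators.  Its partial natural indirect effect is
#' estimated by G-computation while a controlled co-mediator (occupational
#' noise or smoking) follows its natural law under the second wave and
#' education's wave-1 level - i.e. the co-mediator's law is held fixed
#' across the education contrast, so no effect leaks through it.
#'
#' @param data cohort data, complete on model columns.
#' @param spec a [mediation_spec()] whose single mediator is
#'   \code{"education"}.
#' @param control co-mediator to hold at its natural law, usually
#'   \code{"noise"} or \code{"smoking"}.
#' @param config a [gformula_config()].
#' @param bootstrap,seed bootstrap draws and seed for standard errors.
#' @return a \code{"mediation_result"} tagged \code{"partial"}.
#' @export
partial_nie_education <- function(data, spec, control,
                                  config = gformula_config(),
                                  bootstrap = 0, seed = NULL) {
  if (!identical(spec$mediators, "education"))
    stop("partial_nie_education: spec$mediators must be 'education'")
  if (!control %in% names(data))
    stop("control column '", control, "' absent from data")
  data <- apply_stratum(data, spec)
  assert_complete(data, spec)
  if (anyNA(data[[control]]))
    stop("missing values in control mediator '", control,
         "'; run listwise_delete() first")
  assert_binary_exposure(data, spec)
  core <- function(d, mc_seed) {
    cfg <- config; cfg$seed <- mc_seed
    partial_education_point(d, spec, control, cfg)
  }
  est <- core(data, config$seed)
  se <- ci <- NULL
  if (bootstrap > 0) {
    bs <- bootstrap_ci(function(d)
      core(d, sample.int(.Machine$integer.max, 1))$estimates,
      data, n_draws = bootstrap, seed = seed)
    se <- bs$se; ci <- bs$ci_normal
  }
  mediation_result(est$estimates["total"],
                   est$estimates["total"] - est$estimates["nie"],
                   est$estimates["nie"],
                   method = "gformula", stratum = spec$stratum,
                   n_used = nrow(data), se = se, ci = ci,
                   mc_error = est$mc_error, tag = "partial")
}

partial_education_point <- function(data, spec, control, config) {
  x_col <- spec$exposure
  covs <- spec$covariates
  # outcome model: education + controlled co-mediator + covariates
  yspec <- within_spec(spec, mediators = c("education", control),
                       interactions = FALSE)
  yfit <- fit_outcome_model(data, yspec, xm_interactions = FALSE)
  efit <- fit_categorical_model(data, "education",
                                predictors = c(x_col, covs),
                                age_knots = yfit$knots)
  cfit <- fit_categorical_model(data, control,
                                predictors = c(x_col, "education", covs),
                                age_knots = yfit$knots)
  Cdf <- mc_covariates(data, config)
  R <- nrow(Cdf)
  at <- function(x, e = NULL, ctl = NULL) {
    nd <- Cdf
    nd[[x_col]] <- x
    if (!is.null(e)) nd$education <- e
    if (!is.null(ctl)) nd[[control]] <- ctl
    nd
  }
  elv <- efit$levels
  clv <- cfit$levels
  pe <- list(`0` = predict_probs(efit, at(0)),
             `1` = predict_probs(efit, at(1)))
  # control-mediator law given (x = 1, education = e); also (x = 0, e) for
  # the reference regime of the total effect
  pc <- lapply(c(0, 1), function(x)
    lapply(elv, function(e) predict_probs(cfit, at(x, e = e))))
  names(pc) <- c("0", "1")
  ey <- function(x, e, pctl) {
    out <- numeric(R)
    for (k in seq_along(clv))
      out <- out + pctl[, k] * predict_ht(yfit, at(x, e = e, ctl = clv[k]))
    out
  }
  # arm 1: education and control both in the wave-1 world
  arm1 <- numeric(R)
  for (j in seq_along(elv))
    arm1 <- arm1 + pe$`1`[, j] * ey(1, elv[j], pc$`1`[[j]])
  # arm 2: education from the wave-0 law; control keeps its (x = 1, e1) law
  arm2 <- numeric(R)
  for (j in seq_along(elv)) {        # j indexes e1, the control's world
    inner <- numeric(R)
    for (i in seq_along(elv))
      inner <- inner + pe$`0`[, i] * ey(1, elv[i], pc$`1`[[j]])
    arm2 <- arm2 + pe$`1`[, j] * inner
  }
  # reference regime for the total effect: everything in wave 0
  arm0 <- numeric(R)
  for (j in seq_along(elv))
    arm0 <- arm0 + pe$`0`[, j] * ey(0, elv[j], pc$`0`[[j]])
  nie_row <- arm1 - arm2
  list(estimates = c(total = mean(arm1 - arm0), nie = mean(nie_row)),
       mc_error = stats::sd(nie_row) / sqrt(R))
}

#' Test the identification assumptions for specific natural effects
#'
#' Fits the saturated outcome model with all exposure-mediator and
#' exposure-confounder interaction terms and reports joint Wald tests per
#' assumption, plus a likelihood-ratio test of dummy-coded versus
#' linear-score confounder (nonlinearity).  Recommends
#' \code{"no_XM_interaction"} when the exposure-mediator interactions are
#' jointly non-significant, \code{"linear_L_effect"} when the exposure-
#' confounder interaction is absent and linearity of the confounder is not
#' rejected; when both assumption sets fail, the one with the smaller
#' violation (larger p-value) is recommended with a warning flag, with
#' ties going to \code{"no_XM_interaction"}.
#'
#' @param data cohort data, complete on model columns.
#' @param spec a [mediation_spec()] listing the behavioural mediators and
#'   an intermediate confounder.
#' @param alpha significance level for the recommendation (default 0.05).
#' @return object of class \code{"assumption_report"}: a table of per-term
#'   tests, the joint test p-values, the recommended identification and a
#'   \code{violated} flag.
#' @export
test_identification_assumptions <- function(data, spec, alpha = 0.05) {
  data <- apply_stratum(data, spec)
  assert_complete(data, spec)
  if (is.null(spec$intermediate_confounder))
    stop("spec must name an intermediate confounder")
  fit <- fit_outcome_model(data, spec, xm_interactions = TRUE,
                           xl_interaction = TRUE, l_linear = FALSE)
  b <- fit$coefficients; V <- fit$vcov
  x_col <- spec$exposure
  wald <- function(idx) {
    stat <- drop(t(b[idx]) %*% solve(V[idx, idx, drop = FALSE], b[idx]))
    c(statistic = stat, df = length(idx),
      p_value = stats::pchisq(stat, length(idx), lower.tail = FALSE))
  }
  inter_idx <- function(col) grep(paste0("^", x_col, ":", col, "_f"),
                                  names(b))
  rows <- list()
  xm_all <- integer(0)
  for (m in spec$mediators) {
    idx <- inter_idx(m)
    xm_all <- c(xm_all, idx)
    rows[[paste0("XM_", m)]] <- c(wald(idx))
  }
  rows[["XM_joint"]] <- wald(xm_all)
  xl_idx <- inter_idx(spec$intermediate_confounder)
  rows[["XL"]] <- wald(xl_idx)
  # nonlinearity of the confounder: dummy-coded vs linear score
  fdum <- fit_outcome_model(data, spec, xm_interactions = TRUE,
                            xl_interaction = FALSE, l_linear = FALSE)
  flin <- fit_outcome_model(data, spec, xm_interactions = TRUE,
                            xl_interaction = FALSE, l_linear = TRUE)
  nl_stat <- max(0, 2 * (fdum$logLik - flin$logLik))
  nl_df <- fdum$df - flin$df
  rows[["L_nonlinearity"]] <- c(statistic = nl_stat, df = nl_df,
                                p_value = stats::pchisq(nl_stat, nl_df,
                                                        lower.tail = FALSE))
  tab <- do.call(rbind, rows)
  tab <- data.frame(term = rownames(tab), tab, row.names = NULL)
  p_xm <- tab$p_value[tab$term == "XM_joint"]
  p_xl <- tab$p_value[tab$term == "XL"]
  p_nl <- tab$p_value[tab$term == "L_nonlinearity"]
  ok_xm <- p_xm > alpha
  ok_lin <- p_xl > alpha && p_nl > alpha
  violated <- !ok_xm && !ok_lin
  recommended <- if (ok_xm || (violated && p_xm >= min(p_xl, p_nl)))
    "no_XM_interaction" else "linear_L_effect"
  structure(list(tests = tab, recommended = recommended,
                 violated = violated, alpha = alpha,
                 stratum = spec$stratum, n = nrow(data)),
            class = "assumption_report")
}

#' @export
print.assumption_report <- function(x, ...) {
  cat("Identification-assumption tests (stratum ", x$stratum,
      ", n = ", x$n, ")\n", sep = "")
  print(transform(x$tests, statistic = round(statistic, 2),
                  p_value = signif(p_value, 3)), row.names = FALSE)
  cat("recommended:", x$recommended,
      if (x$violated) "(both assumption sets show violations)", "\n")
  invisible(x)
}
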