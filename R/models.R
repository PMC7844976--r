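# Component model fits: Gaussian linear outcome models with restricted
# cubic spline age terms, and baseline-category multinomial logit models
# for the categorical mediators and the intermediate confounder.
#
# Categorical columns are dummy-coded via factor columns with levels fixed
# at fit time (<col>_f), so counterfactual prediction data in which a
# category is constant still maps onto the fitted design.

CAT_COLS <- c("education", "noise", "ear_infections", "smoking")

# add spline columns .age1.. and fixed-level factor columns <col>_f
build_frame <- function(data, knots = NULL, levels_map = list(),
                        cat_cols = intersect(CAT_COLS, names(data))) {
  data <- augment_age(data, knots)
  for (col in cat_cols) {
    lv <- levels_map[[col]]
    if (is.null(lv)) lv <- sort(unique(data[[col]]))
    data[[paste0(col, "_f")]] <- factor(data[[col]], levels = lv)
  }
  attr(data, "levels_map") <- if (length(cat_cols))
    stats::setNames(lapply(cat_cols, function(col)
      levels(data[[paste0(col, "_f")]])), cat_cols) else list()
  data
}

# add restricted-cubic-spline age columns .age1...; knots from data if NULL
augment_age <- function(data, knots = NULL) {
  b <- rcs_basis(data$age, knots = knots)
  for (j in seq_len(ncol(b))) data[[paste0(".age", j)]] <- b[, j]
  attr(data, "age_knots") <- attr(b, "knots")
  data
}

age_terms <- function(spline = TRUE, n_basis = 4) {
  if (!spline) "age" else paste0(".age", seq_len(n_basis))
}

# term name for a column: factor column for categorical, raw otherwise
term_of <- function(col, linear = FALSE) {
  if (!linear && col %in% CAT_COLS) paste0(col, "_f") else col
}

# rhs terms for the outcome model implied by a mediation spec
outcome_rhs <- function(spec,
                        xm_interactions = spec$interactions,
                        xl_interaction = FALSE,
                        l_linear = FALSE,
                        age_spline = TRUE,
                        include_mediators = TRUE) {
  x <- spec$exposure
  terms <- x
  if (include_mediators) {
    med <- vapply(spec$mediators, term_of, "")
    terms <- c(terms, med)
    if (xm_interactions) terms <- c(terms, paste0(x, ":", med))
  }
  L <- spec$intermediate_confounder
  if (!is.null(L)) {
    lterm <- term_of(L, linear = l_linear)
    terms <- c(terms, lterm)
    if (xl_interaction) terms <- c(terms, paste0(x, ":", lterm))
  }
  covs <- setdiff(spec$covariates, "age")
  if ("age" %in% spec$covariates) covs <- c(covs, age_terms(age_spline))
  c(terms, covs)
}

#' Fit the linear outcome model
#'
#' Ordinary least squares for a hearing outcome on exposure, mediators
#' (dummy-coded), the optional intermediate confounder, and baseline
#' covariates with age as a restricted cubic spline (5 knots by default).
#'
#' @param data complete-case cohort data (see [listwise_delete()]).
#' @param spec a [mediation_spec()].
#' @param xm_interactions include exposure-by-mediator interactions
#'   (default: the spec's \code{interactions} flag).
#' @param xl_interaction include exposure-by-confounder interactions.
#' @param l_linear enter the intermediate confounder as a linear ordinal
#'   score instead of dummy-coded.
#' @param age_spline spline age (\code{TRUE}) or linear age (\code{FALSE}).
#' @param include_mediators drop the mediators entirely (for the
#'   total-effect model) when \code{FALSE}.
#' @return object of class \code{"ht_fit"}: the \code{lm} fit plus
#'   coefficients, covariance, log-likelihood, n, family, the spline knots
#'   and the factor levels used (for counterfactual prediction).
#' @export
fit_outcome_model <- function(data, spec,
                              xm_interactions = spec$interactions,
                              xl_interaction = FALSE,
                              l_linear = FALSE,
                              age_spline = TRUE,
                              include_mediators = TRUE) {
  data <- apply_stratum(data, spec)
  assert_complete(data, spec)
  if (any(!is.finite(data[[spec$outcome]])))
    stop("non-finite outcome values in ", spec$outcome)
  data <- build_frame(data)
  rhs <- outcome_rhs(spec, xm_interactions, xl_interaction,
                     l_linear, age_spline, include_mediators)
  fml <- stats::as.formula(paste(spec$outcome, "~", paste(rhs, collapse = " + ")))
  fit <- stats::lm(fml, data = data)
  if (anyNA(stats::coef(fit)))
    stop("rank-deficient outcome design; collinear terms: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  structure(list(fit = fit, formula = fml,
                 coefficients = stats::coef(fit), vcov = stats::vcov(fit),
                 logLik = as.numeric(stats::logLik(fit)),
                 df = attr(stats::logLik(fit), "df"),
                 n_obs = stats::nobs(fit), family = "gaussian linear",
                 knots = attr(data, "age_knots"),
                 levels_map = attr(data, "levels_map")),
            class = "ht_fit")
}

#' Predicted outcome means from a fitted outcome model
#'
#' @param object an \code{"ht_fit"}.
#' @param newdata data frame of model columns (raw integer categories);
#'   spline and factor columns are reconstructed with the knots and levels
#'   stored at fit time.
#' @return numeric vector of predicted means (dB).
#' @export
predict_ht <- function(object, newdata) {
  newdata <- build_frame(newdata, knots = object$knots,
                         levels_map = object$levels_map,
                         cat_cols = names(object$levels_map))
  unname(stats::predict(object$fit, newdata = newdata))
}

#' @export
print.ht_fit <- function(x, ...) {
  cat("<ht_fit> ", deparse(x$formula), "\n  family:", x$family,
      " n =", x$n_obs, " logLik =", format(x$logLik), "\n")
  invisible(x)
}

#' Fit a baseline-category multinomial logit model
#'
#' Used for the categorical mediators and for the intermediate confounder
#' inside the G-computation.  The reference category is the first level
#' (no / never / primary school).
#'
#' @param data complete-case cohort data.
#' @param target categorical target column (>= 2 observed levels).
#' @param predictors character vector of predictor columns; \code{"age"}
#'   expands to the restricted cubic spline basis, categorical columns
#'   (education, noise, ear_infections, smoking) are dummy-coded.
#' @param age_spline spline age or linear age.
#' @param age_knots optional fixed spline knots (reused for prediction).
#' @return object of class \code{"ht_catfit"} with the \code{nnet}
#'   multinomial fit, coefficients, log-likelihood and target levels.
#' @export
fit_categorical_model <- function(data, target, predictors,
                                  age_spline = TRUE, age_knots = NULL) {
  if (anyNA(data[c(target, setdiff(predictors, "age"))]))
    stop("missing values in target or predictors")
  lv <- sort(unique(data[[target]]))
  if (length(lv) < 2) stop("target '", target, "' has fewer than 2 observed levels")
  counts <- table(data[[target]])
  if (any(counts < 5))
    warning("target '", target, "' has categories observed < 5 times (",
            paste(names(counts)[counts < 5], collapse = ", "),
            "); estimates may be unstable - consider collapsing levels")
  data <- build_frame(data, knots = age_knots)
  expand <- function(p) if (p == "age") age_terms(age_spline) else term_of(p)
  rhs <- unlist(lapply(predictors, expand))
  data$.target <- factor(data[[target]], levels = lv)
  fml <- stats::as.formula(paste(".target ~",
                                 paste(c("1", rhs), collapse = " + ")))
  fit <- nnet::multinom(fml, data = data, trace = FALSE, maxit = 200,
                        reltol = 1e-8)
  if (!is.null(fit$convergence) && fit$convergence != 0)
    stop("multinomial fit for '", target, "' did not converge in 200 ",
         "iterations (deviance ", format(2 * fit$value), "); consider ",
         "collapsing sparse categories")
  structure(list(fit = fit, target = target, levels = lv, formula = fml,
                 coefficients = stats::coef(fit),
                 logLik = as.numeric(stats::logLik(fit)),
                 n_obs = nrow(data), family = "categorical logit",
                 knots = attr(data, "age_knots"),
                 levels_map = attr(data, "levels_map"),
                 age_spline = age_spline),
            class = "ht_catfit")
}

#' @export
print.ht_catfit <- function(x, ...) {
  cat("<ht_catfit> ", deparse(x$formula), "\n  target:", x$target,
      " levels:", paste(x$levels, collapse = "/"),
      " n =", x$n_obs, " logLik =", format(x$logLik), "\n")
  invisible(x)
}

#' Predicted class probabilities from a categorical model
#'
#' @param object an \code{"ht_catfit"}.
#' @param newdata data frame of predictor columns (raw integer categories).
#' @return matrix, one row per subject, one column per target level; rows
#'   sum to 1.
#' @export
predict_probs <- function(object, newdata) {
  newdata <- build_frame(newdata, knots = object$knots,
                         levels_map = object$levels_map,
                         cat_cols = names(object$levels_map))
  p <- stats::predict(object$fit, newdata = newdata, type = "probs")
  if (is.null(dim(p)))                    # binary target or single row
    p <- if (length(object$levels) == 2 && nrow(newdata) == length(p))
      cbind(1 - p, p) else matrix(p, nrow = 1)
  colnames(p) <- as.character(object$levels)
  p
}

#' Likelihood-ratio test of spline versus linear age
#'
#' Compares the outcome model with age as a 5-knot restricted cubic spline
#' against the nested model with linear age, on identical rows.
#'
#' @param data complete-case cohort data.
#' @param spec a [mediation_spec()].
#' @param ... passed to [fit_outcome_model()] (interaction switches).
#' @return list with \code{statistic} (twice the log-likelihood
#'   difference), \code{df} (3 for five knots) and \code{p_value}
#'   (chi-square upper tail).
#' @export
lrt_spline_vs_linear <- function(data, spec, ...) {
  f1 <- fit_outcome_model(data, spec, age_spline = TRUE, ...)
  f0 <- fit_outcome_model(data, spec, age_spline = FALSE, ...)
  if (f1$n_obs != f0$n_obs)
    stop("models fitted on different row sets")
  stat <- max(0, 2 * (f1$logLik - f0$logLik))
  df <- f1$df - f0$df
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}
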