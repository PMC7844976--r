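# Joint natural direct/indirect effects via the imputation-based natural
# effect model, and the traditional difference method for comparison.

# container for every estimator's output
mediation_result <- function(total, nde, nie, method, stratum = "all",
                             n_used = NA_integer_, n_dropped = 0L,
                             se = NULL, ci = NULL, mc_error = NA_real_,
                             identification = NULL, tag = NULL) {
  total <- unname(total); nde <- unname(nde)
  if (length(nie) == 1) nie <- unname(nie)
  mp <- if (!is.na(total) && total != 0) nie / total else rep(NA_real_, length(nie))
  structure(list(total_effect = total, nde = nde, nie = nie,
                 mediated_proportion = mp, se = se, ci = ci,
                 mc_error = mc_error, method = method,
                 identification = identification, tag = tag,
                 stratum = stratum, n_used = n_used,
                 n_dropped_missing = n_dropped),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, digits = 3, ...) {
  cat("Mediation result [", x$method,
      if (!is.null(x$identification)) paste0(", ", x$identification),
      "] stratum: ", x$stratum, ", n = ", x$n_used, "\n", sep = "")
  show <- function(label, est, key) {
    line <- sprintf("  %-10s %8s", label, format(round(est, digits)))
    if (!is.null(x$ci) && key %in% rownames(x$ci))
      line <- paste0(line, sprintf("  (95%% CI %s, %s)",
                                   format(round(x$ci[key, 1], digits)),
                                   format(round(x$ci[key, 2], digits))))
    cat(line, "\n")
  }
  show("total", x$total_effect, "total")
  show("NDE", x$nde, "nde")
  if (length(x$nie) == 1) show("NIE", x$nie, "nie")
  else for (m in names(x$nie)) show(paste0("NIE ", m), x$nie[m], paste0("nie_", m))
  mp <- x$mediated_proportion
  if (all(is.na(mp))) cat("  mediated proportion: undefined (total = 0)\n")
  else cat("  mediated proportion:", paste(round(mp, 2), collapse = ", "), "\n")
  invisible(x)
}

# design pieces shared by the lean estimator cores: baseline covariates
# (spline age + optional sex) and per-mediator dummy columns
core_design <- function(data, spec, with_mediators = TRUE) {
  C <- NULL
  if ("age" %in% spec$covariates)
    C <- unclass(rcs_basis(data$age))[, , drop = FALSE]
  if ("sex" %in% spec$covariates) C <- cbind(C, sex = data$sex)
  extra <- setdiff(spec$covariates, c("age", "sex"))
  for (cc in extra) C <- cbind(C, stats::setNames(data[cc], cc))
  M <- NULL; m_of_col <- integer(0)
  if (with_mediators) {
    for (j in seq_along(spec$mediators)) {
      v <- data[[spec$mediators[j]]]
      lv <- sort(unique(v))
      if (length(lv) > 20)
        stop("mediator '", spec$mediators[j], "' has ", length(lv),
             " distinct values; dummy coding expects a categorical column")
      for (l in lv[-1]) {
        M <- cbind(M, as.numeric(v == l))
        m_of_col <- c(m_of_col, j)
      }
    }
  }
  list(C = C, M = M, m_of_col = m_of_col)
}

solve_ols <- function(D, y) {
  f <- stats::lm.fit(D, y)
  b <- f$coefficients
  if (anyNA(b))
    stop("rank-deficient design; collinear columns: ",
         paste(colnames(D)[is.na(b)], collapse = ", "))
  b
}

# point estimates of (total, nde, nie) by the imputation estimator;
# data must be stratum-filtered and complete
joint_nie_core <- function(data, spec, xm_interactions = spec$interactions) {
  y <- data[[spec$outcome]]
  x <- data[[spec$exposure]]
  d <- core_design(data, spec)
  D <- cbind(`(i)` = 1, x = x, d$M, d$C)
  nx <- 2L
  if (xm_interactions && !is.null(d$M)) D <- cbind(D, x * d$M)
  b <- solve_ols(D, y)
  # counterfactual imputations: exposure column (and its interactions)
  # switched to 0 / 1, observed mediator values kept
  D0 <- D; D0[, nx] <- 0
  D1 <- D; D1[, nx] <- 1
  if (xm_interactions && !is.null(d$M)) {
    ic <- ncol(D) - ncol(d$M) + seq_len(ncol(d$M))
    D0[, ic] <- 0
    D1[, ic] <- d$M
  }
  yhat <- c(D0 %*% b, D1 %*% b)
  # natural effect model: imputed Y(x0, M(x*)) on x0 (direct), x* (indirect)
  n <- length(y)
  x0 <- rep(c(0, 1), each = n)
  xstar <- rep(x, 2)
  Cb <- if (is.null(d$C)) NULL else rbind(d$C, d$C)
  N <- cbind(1, x0 = x0, xstar = xstar, Cb)
  g <- solve_ols(N, yhat)
  nde <- unname(g[2]); nie <- unname(g[3])
  c(total = nde + nie, nde = nde, nie = nie)
}

#' Joint natural indirect effect by the imputation-based natural effect model
#'
#' Fits the outcome model with all exposure-by-mediator interaction terms,
#' duplicates every subject at both hypothetical exposure levels, imputes
#' the nested counterfactual outcome Y(x, M(x*)) keeping the observed
#' mediator values, and regresses the imputations on the hypothetical
#' exposure (direct effect), the observed exposure (indirect effect) and
#' the baseline covariates.  The total effect is NDE + NIE by construction
#' (the natural effect model is additive in x and x*).
#'
#' @param data cohort data, complete on all model columns.
#' @param spec a [mediation_spec()]; all its mediators are treated as one
#'   joint block.
#' @param bootstrap number of bootstrap draws for standard errors (0 for
#'   point estimates only; the study design uses 1000).
#' @param seed seed for the bootstrap resampling.
#' @return a \code{"mediation_result"} with the joint NIE.
#' @examples
#' d <- generate_cohort(hunt_config(n_per_wave = 1500, missingness_rate = 0))
#' spec <- mediation_spec("ht_low",
#'   mediators = c("education", "ear_infections", "noise", "smoking"))
#' estimate_joint_nie(d, spec)
#' @export
estimate_joint_nie <- function(data, spec, bootstrap = 0, seed = NULL) {
  data <- apply_stratum(data, spec)
  assert_complete(data, spec)
  assert_binary_exposure(data, spec)
  est <- joint_nie_core(data, spec)
  se <- ci <- NULL
  if (bootstrap > 0) {
    bs <- bootstrap_ci(function(d) joint_nie_core(d, spec), data,
                       n_draws = bootstrap, seed = seed)
    se <- bs$se; ci <- bs$ci_normal
  }
  mediation_result(est["total"], est["nde"], est["nie"],
                   method = "natural_effect_imputation",
                   stratum = spec$stratum, n_used = nrow(data),
                   se = se, ci = ci)
}

#' Traditional difference-method mediation estimate
#'
#' Regresses the outcome on exposure and covariates with and without the
#' mediators; the indirect effect is the drop in the exposure coefficient.
#' Valid only for linear models with no exposure-mediator interaction.
#'
#' @inheritParams estimate_joint_nie
#' @return a \code{"mediation_result"} with method tag
#'   \code{"difference_method"}.
#' @export
difference_method <- function(data, spec, bootstrap = 0, seed = NULL) {
  data <- apply_stratum(data, spec)
  assert_complete(data, spec)
  assert_binary_exposure(data, spec)
  core <- function(d) {
    y <- d[[spec$outcome]]; x <- d[[spec$exposure]]
    des <- core_design(d, spec)
    b_tot <- solve_ols(cbind(1, x = x, des$C), y)
    b_adj <- solve_ols(cbind(1, x = x, des$M, des$C), y)
    total <- unname(b_tot[2]); nde <- unname(b_adj[2])
    c(total = total, nde = nde, nie = total - nde)
  }
  est <- core(data)
  se <- ci <- NULL
  if (bootstrap > 0) {
    bs <- bootstrap_ci(core, data, n_draws = bootstrap, seed = seed)
    se <- bs$se; ci <- bs$ci_normal
  }
  mediation_result(est["total"], est["nde"], est["nie"],
                   method = "difference_method",
                   stratum = spec$stratum, n_used = nrow(data),
                   se = se, ci = ci)
}

#' Mediated proportion
#'
#' The natural indirect effect divided by the total effect.  Reported to
#' two decimals in tables and to the nearest percent in summaries.
#'
#' @param total total effect (dB); must be nonzero.
#' @param nie natural indirect effect (dB).
#' @return \code{nie / total} (unitless).
#' @examples
#' round(mediated_proportion(-2.79, -0.76), 2)   # 0.27
#' @export
mediated_proportion <- function(total, nie) {
  if (any(total == 0))
    stop("mediated proportion undefined: total effect is zero")
  nie / total
}
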