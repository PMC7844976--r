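#' Declare the roles of the analysis variables
#'
#' A mediation specification names the exposure (study wave), the outcome
#' (an averaged hearing threshold), the mediators, the optional
#' exposure-induced intermediate confounder (education, when it is a
#' confounder of the behavioural mediators rather than the mediator of
#' interest), the baseline covariates, and the identification strategy.
#'
#' @param outcome outcome column, typically \code{"ht_low"} or
#'   \code{"ht_high"}.
#' @param mediators character vector of mediator columns, a subset of
#'   \code{c("education", "ear_infections", "noise", "smoking")} (or any
#'   categorical columns of the data).
#' @param exposure binary exposure column (default \code{"wave"},
#'   0 = first wave, 1 = second wave).
#' @param intermediate_confounder optional column (usually
#'   \code{"education"}) that confounds the mediator-outcome relation and
#'   is itself affected by the exposure.  Must not also be listed in
#'   \code{mediators}.
#' @param covariates baseline covariates; age receives a restricted cubic
#'   spline, other columns enter linearly/as given.
#' @param interactions include exposure-by-mediator interaction terms in the
#'   outcome model (the natural-effect estimators default to all of them).
#' @param identification identification strategy when an intermediate
#'   confounder is present: \code{"no_XM_interaction"} (Robins-Greenland:
#'   omit exposure-mediator interactions) or \code{"linear_L_effect"}
#'   (Petersen: confounder enters the outcome model as a linear score with
#'   no exposure-confounder interaction); \code{"none_required"} when no
#'   intermediate confounder is involved.
#' @param stratum \code{"all"}, \code{"women"} or \code{"men"}; sex is a
#'   covariate for \code{"all"} and a row filter otherwise.
#' @return an object of class \code{"mediation_spec"}.
#' @examples
#' mediation_spec("ht_high", mediators = "noise",
#'                intermediate_confounder = "education",
#'                identification = "linear_L_effect")
#' @export
mediation_spec <- function(outcome,
                           mediators,
                           exposure = "wave",
                           intermediate_confounder = NULL,
                           covariates = c("age", "sex"),
                           interactions = TRUE,
                           identification = c("none_required",
                                              "no_XM_interaction",
                                              "linear_L_effect"),
                           stratum = c("all", "women", "men")) {
  identification <- match.arg(identification)
  stratum <- match.arg(stratum)
  if (length(mediators) < 1) stop("mediation_spec: at least one mediator")
  roles <- c(exposure, outcome, mediators, intermediate_confounder, covariates)
  if (anyDuplicated(roles))
    stop("mediation_spec: exposure, outcome, mediators, intermediate ",
         "confounder and covariates must name distinct columns (duplicated: ",
         paste(unique(roles[duplicated(roles)]), collapse = ", "), ")")
  if (!is.null(intermediate_confounder) &&
      intermediate_confounder %in% mediators)
    stop("mediation_spec: intermediate_confounder cannot also be a mediator")
  if (stratum != "all") covariates <- setdiff(covariates, "sex")
  if (stratum == "all" && !"sex" %in% covariates)
    stop("mediation_spec: pooled analyses must adjust for sex")
  structure(list(outcome = outcome, exposure = exposure,
                 mediators = mediators,
                 intermediate_confounder = intermediate_confounder,
                 covariates = covariates, interactions = interactions,
                 identification = identification, stratum = stratum),
            class = "mediation_spec")
}

#' @export
print.mediation_spec <- function(x, ...) {
  cat("Mediation specification\n")
  cat("  exposure   :", x$exposure, " outcome:", x$outcome, "\n")
  cat("  mediators  :", paste(x$mediators, collapse = ", "), "\n")
  if (!is.null(x$intermediate_confounder))
    cat("  intermediate confounder:", x$intermediate_confounder,
        " [", x$identification, "]\n")
  cat("  covariates :", paste(x$covariates, collapse = ", "),
      " stratum:", x$stratum, "\n")
  invisible(x)
}

# filter rows to the spec's stratum; sex column: 0 = female, 1 = male
apply_stratum <- function(data, spec) {
  if (spec$stratum == "all") return(data)
  keep <- if (spec$stratum == "women") data$sex == 0 else data$sex == 1
  out <- data[keep, , drop = FALSE]
  if (nrow(out) == 0) stop("empty stratum: ", spec$stratum)
  out
}

# columns the estimators need complete
model_columns <- function(data, spec) {
  cols <- unique(c(spec$exposure, spec$outcome, spec$mediators,
                   spec$intermediate_confounder, spec$covariates))
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop("columns absent from data: ", paste(missing_cols, collapse = ", "))
  cols
}

assert_complete <- function(data, spec) {
  cols <- model_columns(data, spec)
  bad <- vapply(data[cols], anyNA, logical(1))
  if (any(bad))
    stop("missing values in model columns (",
         paste(names(bad)[bad], collapse = ", "),
         "); run listwise_delete() first")
  invisible(TRUE)
}

assert_binary_exposure <- function(data, spec) {
  x <- data[[spec$exposure]]
  if (!all(x %in% c(0, 1)))
    stop("exposure '", spec$exposure, "' must be coded 0/1")
  if (length(unique(x)) < 2)
    stop("exposure '", spec$exposure, "' has a single observed level")
  invisible(TRUE)
}
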