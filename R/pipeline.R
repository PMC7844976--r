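# Full-study orchestration: complete-case handling, stratified analysis of
# both frequency bands with every estimator, and table-style reporting.

#' Listwise deletion of subjects missing any mediator
#'
#' Drops rows missing any of the spec's mediators (and the intermediate
#' confounder, if named) and reports the complete-case impact: the
#' covariate-adjusted cohort effect before versus after deletion.
#'
#' @param data cohort data.
#' @param spec a [mediation_spec()].
#' @return list with \code{data} (complete cases) and \code{summary}
#'   (n before/dropped, fraction dropped, cohort effect before and after
#'   deletion and their relative difference).
#' @examples
#' d <- generate_cohort(hunt_config(n_per_wave = 800))
#' spec <- mediation_spec("ht_low", mediators = c("noise", "smoking"))
#' listwise_delete(d, spec)$summary[c("n_dropped", "fraction_dropped")]
#' @export
listwise_delete <- function(data, spec) {
  cols <- intersect(c(spec$mediators, spec$intermediate_confounder),
                    names(data))
  if (!length(cols)) stop("no mediator columns present in data")
  keep <- stats::complete.cases(data[cols])
  if (!any(keep)) stop("listwise deletion removed every row")
  cohort_eff <- function(d) {
    d <- apply_stratum(d, spec)
    y <- d[[spec$outcome]]; x <- d[[spec$exposure]]
    des <- core_design(d, spec, with_mediators = FALSE)
    unname(solve_ols(cbind(1, x = x, des$C), y)[2])
  }
  before <- if (spec$outcome %in% names(data)) cohort_eff(data) else NA_real_
  out <- data[keep, , drop = FALSE]
  after <- if (spec$outcome %in% names(data)) cohort_eff(out) else NA_real_
  list(data = out,
       summary = list(n_before = nrow(data), n_dropped = sum(!keep),
                      fraction_dropped = mean(!keep),
                      cohort_effect_before = before,
                      cohort_effect_after = after,
                      relative_change = if (is.na(before) || before == 0)
                        NA_real_ else abs(after - before) / abs(before)))
}

#' Run the full mediation analysis
#'
#' Executes, for each requested stratum and outcome: listwise deletion,
#' the spline-versus-linear age test, the covariate-adjusted cohort
#' effect, the joint natural indirect effect (imputation-based natural
#' effect model, with the traditional difference method alongside), the
#' identification-assumption tests, and per-mediator specific natural
#' indirect effects by G-computation (education as the partial effect
#' controlling a co-mediator; ear infections without an intermediate
#' confounder; noise and smoking with education as intermediate
#' confounder under the per-stratum recommended identification).
#' Mediated proportions use the cohort effect as denominator and are
#' suppressed when the total is indistinguishable from zero (within two
#' standard errors).
#'
#' @param data cohort data frame (may contain missing mediators).
#' @param config list of settings: \code{outcomes} (default
#'   \code{c("ht_low", "ht_high")}), \code{mediators} (default the four
#'   study mediators), \code{strata} (default all/women/men),
#'   \code{bootstrap} draws for the joint estimator (default 200),
#'   \code{bootstrap_specific} draws for the G-computation estimators
#'   (default 0: Monte Carlo error only), \code{mc_replicates} (default
#'   \code{max(n, 20000)}), \code{education_control} co-mediator for the
#'   partial education effect (default \code{"noise"}), \code{seed}.
#' @return object of class \code{"analysis_report"}: per-block results,
#'   a tidy results table (\code{$table}), and provenance.
#' @export
run_full_analysis <- function(data, config = list()) {
  cfg <- utils::modifyList(list(
    outcomes = c("ht_low", "ht_high"),
    mediators = c("education", "ear_infections", "noise", "smoking"),
    strata = c("all", "women", "men"),
    bootstrap = 200, bootstrap_specific = 0,
    mc_replicates = NULL, education_control = "noise",
    seed = 1L, alpha = 0.05), config)
  missing_meds <- setdiff(cfg$mediators, names(data))
  if (length(missing_meds))
    stop("mediators absent from data: ", paste(missing_meds, collapse = ", "))
  behavioural <- setdiff(cfg$mediators, "education")
  blocks <- list()
  rows <- list()
  seed_k <- 0L
  next_seed <- function() {
    seed_k <<- seed_k + 1L
    (cfg$seed + 104729L * seed_k) %% .Machine$integer.max
  }
  for (stratum in cfg$strata) {
    for (outcome in cfg$outcomes) {
      block <- tryCatch(
        analyse_block(data, outcome, stratum, cfg, behavioural, next_seed),
        error = function(e) {
          warning("stage failed [", stratum, ", ", outcome, "]: ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(block)) next
      blocks[[stratum]][[outcome]] <- block
      rows[[paste(stratum, outcome)]] <- block_rows(block, stratum, outcome)
    }
  }
  structure(list(blocks = blocks,
                 table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 provenance = list(
                   package = "htmediate",
                   version = as.character(utils::packageVersion("htmediate")),
                   seed = cfg$seed, config = cfg,
                   timestamp = format(Sys.time(), tz = "UTC"))),
            class = "analysis_report")
}

analyse_block <- function(data, outcome, stratum, cfg, behavioural,
                          next_seed) {
  joint_spec <- mediation_spec(outcome, mediators = cfg$mediators,
                               stratum = stratum)
  ld <- listwise_delete(data, joint_spec)
  d <- apply_stratum(ld$data, joint_spec)
  if (nrow(d) == 0) stop("empty stratum")
  gcfg <- function() gformula_config(mc_replicates = cfg$mc_replicates %||%
                                       max(nrow(d), 20000L),
                                     seed = next_seed())
  respec <- function(...) mediation_spec(outcome, ..., stratum = stratum)

  lrt <- lrt_spline_vs_linear(d, joint_spec)

  # cohort effect: plain covariate-adjusted regression (total-effect model)
  tot_fit <- fit_outcome_model(d, joint_spec, include_mediators = FALSE)
  ce <- unname(tot_fit$coefficients[joint_spec$exposure])
  ce_se <- sqrt(diag(tot_fit$vcov))[joint_spec$exposure]
  cohort <- list(estimate = ce, se = unname(ce_se),
                 ci = c(ce - 1.96 * ce_se, ce + 1.96 * ce_se))
  total_ok <- abs(ce) >= 2 * ce_se     # proportion guard

  joint <- estimate_joint_nie(d, joint_spec, bootstrap = cfg$bootstrap,
                              seed = next_seed())
  diffm <- difference_method(d, joint_spec)

  assum_spec <- respec(mediators = behavioural,
                       intermediate_confounder = "education")
  assum <- test_identification_assumptions(d, assum_spec, alpha = cfg$alpha)

  specific <- list()
  for (m in behavioural) {
    sp <- if (m == "ear_infections")
      respec(mediators = m)
    else
      respec(mediators = m, intermediate_confounder = "education",
             identification = assum$recommended)
    specific[[m]] <- gformula_specific_nie(
      d, sp, gcfg(), bootstrap = cfg$bootstrap_specific, seed = next_seed())
  }
  if ("education" %in% cfg$mediators) {
    sp <- respec(mediators = "education")
    specific[["education"]] <- partial_nie_education(
      d, sp, control = cfg$education_control, config = gcfg(),
      bootstrap = cfg$bootstrap_specific, seed = next_seed())
  }
  list(n_used = nrow(d), missingness = ld$summary, lrt = lrt,
       cohort_effect = cohort, total_ok = total_ok, joint = joint,
       difference = diffm,
       assumptions = list(recommended = assum$recommended,
                          violated = assum$violated, tests = assum$tests),
       specific = specific)
}

block_rows <- function(block, stratum, outcome) {
  ce <- block$cohort_effect
  prop <- function(nie) if (block$total_ok)
    round(mediated_proportion(ce$estimate, nie), 2) else NA_real_
  row <- function(quantity, est, lo, hi, mp, method, note = "") {
    data.frame(stratum = stratum, outcome = outcome, quantity = quantity,
               estimate = round(est, 2),
               ci_low = round(lo, 2), ci_high = round(hi, 2),
               mediated_proportion = mp, method = method, note = note,
               stringsAsFactors = FALSE)
  }
  j <- block$joint
  jci <- if (!is.null(j$ci)) j$ci["nie", ] else c(NA, NA)
  out <- list(
    row("cohort_effect", ce$estimate, ce$ci[1], ce$ci[2], NA_real_,
        "adjusted_regression"),
    row("nie_joint", j$nie, jci[1], jci[2], prop(j$nie),
        "natural_effect_imputation"),
    row("nie_joint_difference_method", block$difference$nie, NA, NA,
        prop(block$difference$nie), "difference_method"))
  for (m in names(block$specific)) {
    s <- block$specific[[m]]
    sci <- if (!is.null(s$ci)) s$ci["nie", ] else c(NA, NA)
    out[[length(out) + 1]] <-
      row(paste0("nie_", m), s$nie, sci[1], sci[2], prop(s$nie),
          s$method, note = paste0(c(s$identification, s$tag), collapse = ","))
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Mediation analysis report (seed ", x$provenance$seed, ")\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write an analysis report to disk
#'
#' @param report an \code{"analysis_report"}.
#' @param outdir output directory (created if absent); writes
#'   \code{report.json} and \code{tables.tsv}.
#' @return \code{outdir}, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ser <- report
  ser$blocks <- lapply(ser$blocks, function(bs) lapply(bs, function(b) {
    b$joint <- unclass(b$joint); b$difference <- unclass(b$difference)
    b$specific <- lapply(b$specific, unclass)
    b
  }))
  jsonlite::write_json(unclass(ser), file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  utils::write.table(report$table, file.path(outdir, "tables.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(outdir)
}
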