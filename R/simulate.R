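#' Simulate a two-wave cross-sectional cohort
#'
#' Draws \code{2 * n_per_wave} subjects from the configured data-generating
#' model: truncated-normal age, Bernoulli sex, categorical education per
#' (wave, sex), categorical-logit mediators given wave, sex, education and
#' age, and Gaussian linear hearing outcomes.  Missingness (if configured)
#' blanks one uniformly chosen mediator for a random subset of subjects.
#' Identical \code{(config, seed)} give bit-identical output.
#'
#' @param config a [generator_config()].
#' @param seed integer; defaults to \code{config$seed}.
#' @return data frame with columns \code{subject_id}, \code{wave} (0/1),
#'   \code{age} (years), \code{sex} (0 = female, 1 = male),
#'   \code{education} (1-4), one integer column per configured mediator,
#'   and one numeric column (dB) per configured outcome.
#' @examples
#' d <- generate_cohort(hunt_config(n_per_wave = 200))
#' head(d)
#' @export
generate_cohort <- function(config, seed = config$seed) {
  validate_generator_config(config)
  set.seed(seed)
  n <- as.integer(config$n_per_wave)
  N <- 2L * n
  wave <- rep(0:1, each = n)
  wi <- wave + 1L

  # truncated normal age via inverse-cdf on the truncated range
  mu <- config$age$mean[wi]; sd <- config$age$sd[wi]
  plo <- stats::pnorm(config$age$min, mu, sd)
  phi <- stats::pnorm(config$age$max, mu, sd)
  age <- stats::qnorm(plo + stats::runif(N) * (phi - plo), mu, sd)
  age <- pmin(pmax(age, config$age$min), config$age$max)

  sex <- as.integer(stats::runif(N) >= config$p_female[wi])  # 1 = male
  si <- sex + 1L

  draw_cat <- function(prob) {           # prob: N x K row-stochastic
    K <- ncol(prob)
    u <- stats::runif(nrow(prob))
    cum <- prob
    for (l in seq_len(K - 1) + 1L) cum[, l] <- cum[, l - 1L] + prob[, l]
    as.integer(rowSums(u > cum) + 1L)
  }

  edu_prob <- matrix(0, N, 4)
  for (l in 1:4) edu_prob[, l] <- config$education_probs[cbind(wi, si, l)]
  education <- draw_cat(edu_prob)

  out <- data.frame(subject_id = sprintf("S%06d", seq_len(N)),
                    wave = wave, age = age, sex = sex,
                    education = education,
                    stringsAsFactors = FALSE)

  edu_c <- education - 2.5               # centred ordinal score
  age_c <- (age - 50) / 10
  for (m in names(config$mediator_models)) {
    mm <- config$mediator_models[[m]]
    K <- mm$levels
    base <- matrix(0, N, K)
    for (l in 1:K) base[, l] <- mm$baseline[cbind(wi, si, l)]
    eta <- log(base[, -1, drop = FALSE] / base[, 1])
    if (!is.null(mm$edu_coef))
      eta <- eta + outer(edu_c, mm$edu_coef)
    if (!is.null(mm$age_coef))
      eta <- eta + outer(age_c, mm$age_coef)
    expo <- cbind(1, exp(eta))
    out[[m]] <- draw_cat(expo / rowSums(expo))
  }

  for (y in names(config$outcome_models)) {
    om <- config$outcome_models[[y]]
    mu_y <- om$intercept + om$wave * wave + om$sex_male * sex +
      om$age[1] * age_c + om$age[2] * age_c^2 +
      om$education[education]
    if (!is.null(om$wave_x_education))
      mu_y <- mu_y + wave * om$wave_x_education[education]
    for (m in names(config$mediator_models)) {
      mu_y <- mu_y + om[[m]][out[[m]]]
      if (!is.null(om$wave_x[[m]]))
        mu_y <- mu_y + wave * om$wave_x[[m]][out[[m]]]
    }
    out[[y]] <- mu_y + stats::rnorm(N, 0, om$residual_sd)
  }

  if (config$missingness_rate > 0) {
    meds <- names(config$mediator_models)
    hit <- stats::runif(N) < config$missingness_rate
    which_med <- sample(length(meds), N, replace = TRUE)
    for (j in seq_along(meds)) {
      idx <- hit & which_med == j
      out[[meds[j]]][idx] <- NA_integer_
    }
  }
  attr(out, "generator_seed") <- as.integer(seed)
  out
}

#' Average per-ear audiometric thresholds into the two outcome bands
#'
#' The low-frequency outcome averages both ears over 0.5, 1 and 2 kHz; the
#' high-frequency outcome averages both ears over 3, 4 and 6 kHz.
#'
#' @param left,right named numeric vectors (one subject) or matrices /
#'   data frames (one row per subject) of thresholds in dB, with names or
#'   column names among \code{"0.5", "1", "2", "3", "4", "6"} (kHz).
#' @return for vector input, named numeric \code{c(ht_low, ht_high)}; for
#'   matrix input, a two-column data frame.
#' @examples
#' average_ht(left  = c("0.5" = 0, "1" = 0, "2" = 0, "3" = 10, "4" = 20, "6" = 30),
#'            right = c("0.5" = 6, "1" = 6, "2" = 6, "3" = 10, "4" = 20, "6" = 30))
#' @export
average_ht <- function(left, right) {
  lowf <- c("0.5", "1", "2"); highf <- c("3", "4", "6")
  as_mat <- function(x, ear) {
    if (is.null(dim(x))) x <- matrix(x, 1, dimnames = list(NULL, names(x)))
    x <- as.matrix(x)
    need <- c(lowf, highf)
    missing_cells <- setdiff(need, colnames(x))
    if (length(missing_cells))
      stop("average_ht: missing ", ear, "-ear frequencies (kHz): ",
           paste(missing_cells, collapse = ", "))
    if (anyNA(x[, need]))
      stop("average_ht: missing threshold values in ", ear, " ear")
    x[, need, drop = FALSE]
  }
  L <- as_mat(left, "left"); R <- as_mat(right, "right")
  if (nrow(L) != nrow(R)) stop("average_ht: ears have different row counts")
  ht_low  <- (rowSums(L[, lowf, drop = FALSE]) +
              rowSums(R[, lowf, drop = FALSE])) / 6
  ht_high <- (rowSums(L[, highf, drop = FALSE]) +
              rowSums(R[, highf, drop = FALSE])) / 6
  if (nrow(L) == 1L) c(ht_low = ht_low, ht_high = ht_high)
  else data.frame(ht_low = ht_low, ht_high = ht_high)
}

#' Write a cohort table with a sidecar schema
#'
#' Writes comma-delimited UTF-8 text plus \code{<path>.schema.json}
#' recording category labels and codes.
#'
#' @param data cohort data frame from [generate_cohort()].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  schema <- list(
    columns = names(data),
    coding = list(
      wave = list("0" = "wave 1 (reference)", "1" = "wave 2"),
      sex = list("0" = "female", "1" = "male"),
      education = list("1" = "primary", "2" = "secondary",
                       "3" = "university < 4y", "4" = "university >= 4y"),
      noise = list("1" = "never", "2" = "< 5 h/week", "3" = "5-15 h/week",
                   "4" = "> 15 h/week"),
      ear_infections = list("1" = "no", "2" = "maybe", "3" = "yes"),
      smoking = list("1" = "never", "2" = "former", "3" = "current")),
    units = list(age = "years", ht_low = "dB", ht_high = "dB"))
  jsonlite::write_json(schema, paste0(path, ".schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a cohort table written by [write_cohort()]
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
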