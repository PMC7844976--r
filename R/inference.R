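#' Nonparametric bootstrap standard errors and confidence intervals
#'
#' Case-resampling bootstrap at the subject level (waves resampled jointly
#' within the pooled data, since the wave indicator is a fixed covariate).
#' The standard error is the standard deviation of the bootstrap
#' replicates; the primary 95\% interval is the normal approximation
#' (point +/- 1.96 SE), with the percentile interval also returned.  The
#' study design uses 1000 draws.
#'
#' @param estimator function taking a data frame and returning a finite
#'   scalar or a named numeric vector.
#' @param data subject-level data frame.
#' @param n_draws number of bootstrap resamples (>= 2).
#' @param seed integer seed; identical seeds give identical resamples.
#' @param level confidence level (default 0.95).
#' @return list with \code{estimate}, \code{se}, \code{ci_normal},
#'   \code{ci_percentile} (matrices with lower/upper columns),
#'   \code{n_draws}, \code{n_failed} and the replicate matrix
#'   \code{replicates} (draws in rows).
#' @examples
#' d <- data.frame(v = rnorm(200))
#' bootstrap_ci(function(x) mean(x$v), d, n_draws = 200, seed = 1)$se
#' @export
bootstrap_ci <- function(estimator, data, n_draws = 1000, seed = NULL,
                         level = 0.95) {
  if (n_draws < 2) stop("bootstrap_ci: n_draws must be >= 2")
  point <- estimator(data)
  if (!is.numeric(point) || anyNA(point) || any(!is.finite(point)))
    stop("bootstrap_ci: estimator must return finite values on the full data")
  if (is.null(names(point)))
    names(point) <- if (length(point) == 1) "estimate"
                    else paste0("q", seq_along(point))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data)
  reps <- matrix(NA_real_, n_draws, length(point),
                 dimnames = list(NULL, names(point)))
  failures <- character(0)
  for (b in seq_len(n_draws)) {
    idx <- sample.int(n, n, replace = TRUE)
    val <- tryCatch(estimator(data[idx, , drop = FALSE]),
                    error = function(e) conditionMessage(e))
    if (is.character(val)) failures <- c(failures, val)
    else reps[b, ] <- val
  }
  if (length(failures) > 0.05 * n_draws)
    stop("bootstrap_ci: estimator failed on ", length(failures), "/",
         n_draws, " resamples; first failure: ", failures[1])
  ok <- stats::complete.cases(reps)
  se <- apply(reps[ok, , drop = FALSE], 2, stats::sd)
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci_n <- cbind(lower = point - z * se, upper = point + z * se)
  qs <- t(apply(reps[ok, , drop = FALSE], 2, stats::quantile,
                probs = c((1 - level) / 2, 1 - (1 - level) / 2)))
  ci_p <- cbind(lower = qs[, 1], upper = qs[, 2])
  rownames(ci_n) <- rownames(ci_p) <- names(point)
  list(estimate = point, se = se, ci_normal = ci_n, ci_percentile = ci_p,
       n_draws = n_draws, n_failed = length(failures), replicates = reps)
}
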