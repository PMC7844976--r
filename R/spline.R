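#' Restricted cubic spline basis for age adjustment
#'
#' Computes a restricted cubic (natural) spline basis in the truncated-power
#' parameterisation with Harrell's normalisation.  With \code{k} knots the
#' basis has \code{k - 1} columns: the linear term plus \code{k - 2}
#' nonlinear terms, each exactly linear beyond the boundary knots.  Default
#' knots sit at the 0.05, 0.275, 0.50, 0.725 and 0.95 quantiles of the
#' observed distribution, the standard placement for five knots in
#' epidemiological covariate adjustment.
#'
#' @param x numeric vector of ages (years) at which to evaluate the basis.
#' @param knots numeric vector of at least 3 strictly increasing knot
#'   locations; if \code{NULL}, placed by [rcs_knots()] on \code{x}.
#' @param n_knots number of knots when \code{knots} is \code{NULL}.
#' @return numeric matrix with \code{length(knots) - 1} columns and a
#'   \code{"knots"} attribute, class \code{"rcs_basis"}.  Column 1 is
#'   \code{x} itself; columns 2+ are the normalised nonlinear terms.
#' @examples
#' b <- rcs_basis(runif(200, 20, 101))
#' attr(b, "knots")
#' @export
rcs_basis <- function(x, knots = NULL, n_knots = 5) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop("rcs_basis: ages must be finite and non-missing")
  if (is.null(knots)) knots <- rcs_knots(x, n_knots)
  k <- length(knots)
  if (k < 3) stop("rcs_basis: need at least 3 knots")
  if (any(diff(knots) <= 0)) stop("rcs_basis: knots must be strictly increasing")
  tk  <- knots[k]
  tk1 <- knots[k - 1]
  nrm <- (tk - knots[1])^2            # Harrell scale normalisation
  cub <- function(u) pmax(u, 0)^3
  out <- matrix(0, length(x), k - 1)
  out[, 1] <- x
  for (j in seq_len(k - 2)) {
    tj <- knots[j]
    out[, j + 1] <- (cub(x - tj) -
                     cub(x - tk1) * (tk - tj) / (tk - tk1) +
                     cub(x - tk)  * (tk1 - tj) / (tk - tk1)) / nrm
  }
  colnames(out) <- paste0("age", seq_len(k - 1))
  attr(out, "knots") <- knots
  class(out) <- c("rcs_basis", class(out))
  out
}

#' Default knot placement for a restricted cubic spline
#'
#' @param x numeric vector of observed values.
#' @param n_knots number of knots (default 5).
#' @return numeric vector of knot locations at the Harrell default quantiles
#'   (for 5 knots: 0.05, 0.275, 0.50, 0.725, 0.95).
#' @export
rcs_knots <- function(x, n_knots = 5) {
  if (anyNA(x) || any(!is.finite(x))) stop("rcs_knots: non-finite values")
  if (length(unique(x)) < n_knots)
    stop("rcs_knots: fewer distinct values (", length(unique(x)),
         ") than knots (", n_knots, ")")
  probs <- switch(as.character(n_knots),
    "3" = c(0.10, 0.50, 0.90),
    "4" = c(0.05, 0.35, 0.65, 0.95),
    "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
    seq(0.05, 0.95, length.out = n_knots))
  kn <- unname(stats::quantile(x, probs, type = 7))
  if (any(diff(kn) <= 0))
    stop("rcs_knots: tied quantiles; distribution too discrete for ", n_knots,
         " knots")
  kn
}
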