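#' Legendre polynomial basis on a covariate range
#'
#' Constructs a Legendre polynomial basis of the given degree over a covariate
#' interval \code{[x_min, x_max]} (degrees Celsius in the intended use). The
#' covariate is rescaled to \code{t = 2 (x - x_min) / (x_max - x_min) - 1}
#' before evaluating the polynomials, as is standard in random-regression
#' test-day models. Under the default \code{"normalized"} convention the k-th
#' basis function is \code{sqrt((2k + 1) / 2) * P_k(t)}, which makes the basis
#' orthonormal on \code{[-1, 1]}; \code{"standard"} uses the plain Legendre
#' polynomials \code{P_k}.
#'
#' @param x_min,x_max Covariate range; \code{x_min < x_max}. Evaluation outside
#'   this range is an error (the basis is never extrapolated).
#' @param degree Polynomial degree (default 2, i.e. intercept + linear +
#'   quadratic).
#' @param normalization \code{"normalized"} (default) or \code{"standard"}.
#' @return An object of class \code{"legendre_basis"}.
#' @examples
#' b <- legendre_basis(0, 30)
#' eval_basis(b, c(10, 25))
#' @export
legendre_basis <- function(x_min, x_max, degree = 2,
                           normalization = c("normalized", "standard")) {
  normalization <- match.arg(normalization)
  if (!is.finite(x_min) || !is.finite(x_max) || x_min >= x_max) {
    abort("`x_min` must be finite and strictly less than `x_max`.")
  }
  if (degree < 0 || degree != round(degree)) abort("`degree` must be a non-negative integer.")
  structure(
    list(x_min = x_min, x_max = x_max, degree = degree,
         normalization = normalization),
    class = "legendre_basis"
  )
}

#' @export
print.legendre_basis <- function(x, ...) {
  cat(sprintf("Legendre basis: degree %d (%s) on [%g, %g]\n",
              x$degree, x$normalization, x$x_min, x$x_max))
  invisible(x)
}

# P_0..P_deg(t) by the three-term recurrence; t in [-1, 1], returns matrix
legendre_poly <- function(t, deg) {
  P <- matrix(0, length(t), deg + 1L)
  P[, 1L] <- 1
  if (deg >= 1L) P[, 2L] <- t
  if (deg >= 2L) {
    for (k in 1L:(deg - 1L)) {
      P[, k + 2L] <- ((2 * k + 1) * t * P[, k + 1L] - k * P[, k]) / (k + 1)
    }
  }
  P
}

# dP_k/dt via P'_{k+1} = (2k + 1) P_k + P'_{k-1}
legendre_poly_deriv <- function(t, deg) {
  P <- legendre_poly(t, deg)
  dP <- matrix(0, length(t), deg + 1L)
  if (deg >= 1L) dP[, 2L] <- 1
  if (deg >= 2L) {
    for (k in 1L:(deg - 1L)) {
      dP[, k + 2L] <- (2 * k + 1) * P[, k + 1L] + dP[, k]
    }
  }
  dP
}

rescale_x <- function(basis, x) 2 * (x - basis$x_min) / (basis$x_max - basis$x_min) - 1

basis_norms <- function(basis) {
  k <- 0:basis$degree
  if (basis$normalization == "normalized") sqrt((2 * k + 1) / 2) else rep(1, length(k))
}

#' Evaluate a Legendre basis
#'
#' @param basis A \code{\link{legendre_basis}}.
#' @param x Covariate values, all within \code{[x_min, x_max]}.
#' @return Matrix with one row per value of \code{x} and \code{degree + 1}
#'   columns.
#' @export
eval_basis <- function(basis, x) {
  if (!inherits(basis, "legendre_basis")) abort("`basis` must be a legendre_basis.")
  if (any(!is.finite(x))) abort("`x` must be finite.")
  eps <- 1e-9 * (basis$x_max - basis$x_min)
  if (any(x < basis$x_min - eps | x > basis$x_max + eps)) {
    abort(sprintf("covariate value outside basis range [%g, %g]; the basis is not extrapolated.",
                  basis$x_min, basis$x_max))
  }
  t <- pmin(1, pmax(-1, rescale_x(basis, x)))
  P <- legendre_poly(t, basis$degree)
  sweep(P, 2L, basis_norms(basis), `*`)
}

#' Evaluate the derivative of a Legendre basis with respect to the covariate
#'
#' Includes the chain-rule factor \code{2 / (x_max - x_min)} so the returned
#' values are derivatives with respect to \code{x} (per degree Celsius), not
#' with respect to the rescaled argument.
#'
#' @inheritParams eval_basis
#' @return Matrix with one row per value of \code{x}.
#' @export
eval_basis_deriv <- function(basis, x) {
  if (!inherits(basis, "legendre_basis")) abort("`basis` must be a legendre_basis.")
  eps <- 1e-9 * (basis$x_max - basis$x_min)
  if (any(x < basis$x_min - eps | x > basis$x_max + eps)) {
    abort(sprintf("covariate value outside basis range [%g, %g]; the basis is not extrapolated.",
                  basis$x_min, basis$x_max))
  }
  t <- pmin(1, pmax(-1, rescale_x(basis, x)))
  dP <- legendre_poly_deriv(t, basis$degree)
  jac <- 2 / (basis$x_max - basis$x_min)
  sweep(dP, 2L, basis_norms(basis), `*`) * jac
}
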