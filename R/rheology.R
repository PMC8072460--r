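#' Carreau blood rheology model
#'
#' Shear-thinning viscosity law for venous blood,
#' \deqn{\mu(\dot\gamma) = \mu_\infty + (\mu_0-\mu_\infty)\,[1+(\lambda\dot\gamma)^2]^{(n-1)/2},}
#' interpolating between the zero-shear viscosity `mu0` and the infinite-shear
#' viscosity `mu_inf`. The defaults are the standard Carreau constants for
#' blood used throughout this package; portal venous flow is slow enough that
#' the shear-thinning branch matters (wall shear rates of order 10--100 1/s).
#'
#' @param mu0 zero-shear viscosity (Pa s)
#' @param mu_inf infinite-shear viscosity (Pa s)
#' @param lambda relaxation time (s)
#' @param n power index (dimensionless, `0 < n < 1` for shear thinning)
#' @param rho fluid density (kg/m^3)
#' @return An object of class `rheology_model`.
#' @examples
#' rh <- rheology_model()
#' carreau_viscosity(c(0, 70.3, 1e6), rh)
#' @export
rheology_model <- function(mu0 = 0.056, mu_inf = 0.00345, lambda = 3.313,
                           n = 0.3568, rho = 1060) {
  stopifnot(mu0 > 0, mu_inf > 0, mu_inf <= mu0, lambda >= 0, rho > 0)
  if (mu_inf < mu0 && (n <= 0 || n >= 1))
    stop("shear-thinning Carreau model requires 0 < n < 1")
  structure(list(mu0 = mu0, mu_inf = mu_inf, lambda = lambda, n = n, rho = rho),
            class = "rheology_model")
}

#' @export
print.rheology_model <- function(x, ...) {
  cat(sprintf(
    "Carreau rheology: mu0 = %g Pa s, mu_inf = %g Pa s, lambda = %g s, n = %g, rho = %g kg/m^3\n",
    x$mu0, x$mu_inf, x$lambda, x$n, x$rho))
  invisible(x)
}

#' Evaluate the Carreau viscosity
#'
#' @param shear_rate non-negative shear rate(s), 1/s
#' @param model a [rheology_model()]
#' @return viscosity in Pa s, bounded by `[mu_inf, mu0]`
#' @export
carreau_viscosity <- function(shear_rate, model = rheology_model()) {
  if (any(shear_rate < 0)) stop("shear rate must be non-negative")
  x <- model$lambda * shear_rate
  model$mu_inf + (model$mu0 - model$mu_inf) * (1 + x^2)^((model$n - 1) / 2)
}

#' Newtonian limit of the rheology model
#'
#' Convenience constructor with `mu0 = mu_inf = mu`, used for analytic
#' (Poiseuille) solver validation.
#'
#' @param mu constant viscosity (Pa s)
#' @param rho density (kg/m^3)
#' @export
newtonian_model <- function(mu = 0.00345, rho = 1060) {
  rheology_model(mu0 = mu, mu_inf = mu, lambda = 0, n = 0.5, rho = rho)
}
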