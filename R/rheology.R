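#' Quemada blood rheology parameters
#'
#' Parameter set for the Quemada shear-thinning viscosity law
#' `mu(gdot) = mu_p * (1 - 0.5 * k(gdot) * hct)^-2` with shear-dependent
#' intrinsic viscosity
#' `k(gdot) = (k0 + kinf * sqrt(gdot/gamma_c)) / (1 + sqrt(gdot/gamma_c))`.
#' Defaults are standard literature values for whole blood at 45%
#' hematocrit; all are configurable.
#'
#' @param mu_plasma plasma viscosity (Pa s), default 1.32e-3.
#' @param hematocrit red-cell volume fraction in `[0, 1)`, default 0.45.
#' @param k0 zero-shear intrinsic viscosity limit, default 4.33.
#' @param kinf infinite-shear intrinsic viscosity limit, default 2.07.
#' @param gamma_c critical shear rate (1/s), default 1.88.
#' @param gamma_floor lower floor applied to shear rates (1/s) to avoid the
#'   zero-shear singularity in quiescent regions, default 1e-3.
#' @return a list of class `rheology_params`.
#' @export
rheology_params <- function(mu_plasma = 1.32e-3, hematocrit = 0.45,
                            k0 = 4.33, kinf = 2.07, gamma_c = 1.88,
                            gamma_floor = 1e-3) {
  if (mu_plasma <= 0) stop_pahemo("Plasma viscosity must be positive.")
  if (hematocrit < 0 || hematocrit >= 1) {
    stop_pahemo("Hematocrit must lie in [0, 1).")
  }
  if (gamma_c <= 0) stop_pahemo("`gamma_c` must be positive.")
  if (0.5 * kinf * hematocrit >= 1) {
    stop_pahemo("0.5 * kinf * hematocrit must be < 1 for a finite high-shear viscosity.")
  }
  structure(
    list(mu_plasma = mu_plasma, hematocrit = hematocrit, k0 = k0,
         kinf = kinf, gamma_c = gamma_c, gamma_floor = gamma_floor),
    class = "rheology_params"
  )
}

#' Newtonian rheology helper
#'
#' A degenerate parameter set with zero hematocrit, so the Quemada law
#' collapses to a constant viscosity `mu`.
#'
#' @param mu dynamic viscosity (Pa s).
#' @export
newtonian_params <- function(mu = 3.5e-3) {
  rheology_params(mu_plasma = mu, hematocrit = 0)
}

#' Quemada apparent viscosity
#'
#' @param shear_rate shear rate(s) (1/s), non-negative; values below the
#'   configured floor are clamped to it.
#' @param params a [rheology_params()].
#' @return dynamic viscosity (Pa s), same length as `shear_rate`.
#' @examples
#' quemada_viscosity(100, rheology_params())
#' @export
quemada_viscosity <- function(shear_rate, params = rheology_params()) {
  if (any(shear_rate < 0)) stop_pahemo("Shear rate must be non-negative.")
  g <- pmax(shear_rate, params$gamma_floor)
  s <- sqrt(g / params$gamma_c)
  k <- (params$k0 + params$kinf * s) / (1 + s)
  frac <- 1 - 0.5 * k * params$hematocrit
  if (any(frac <= 0)) {
    stop_pahemo("Quemada parameters give unbounded viscosity at the floored shear rate.")
  }
  params$mu_plasma / frac^2
}

#' Viscosity bounds of a Quemada parameter set
#'
#' High-shear (`mu_inf`) and zero-shear (`mu_0`, possibly infinite) limits of
#' the viscosity law, used as reference viscosities and solver stability
#' bounds.
#'
#' @param params a [rheology_params()].
#' @return named numeric vector `c(mu_inf = , mu_0 = )` (Pa s).
#' @export
viscosity_bounds <- function(params = rheology_params()) {
  f_inf <- 1 - 0.5 * params$kinf * params$hematocrit
  f_0 <- 1 - 0.5 * params$k0 * params$hematocrit
  mu_0 <- if (f_0 <= 0) Inf else params$mu_plasma / f_0^2
  c(mu_inf = params$mu_plasma / f_inf^2, mu_0 = mu_0)
}
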