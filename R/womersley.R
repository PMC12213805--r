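#' Womersley pulsatile pipe-flow velocity
#'
#' Exact axial velocity of laminar pulsatile flow in a rigid circular tube
#' driven by a prescribed volumetric flow waveform given as Fourier
#' harmonics (see [flow_harmonics()]).  The zero-frequency harmonic yields
#' the Poiseuille profile `u = 2*Q0/(pi R^2) (1 - (r/R)^2)`; each oscillatory
#' harmonic `k` contributes the Womersley solution at Womersley number
#' `alpha_k = R * sqrt(k * w / nu)`, normalised so that the cross-sectional
#' integral of the velocity recovers the prescribed flow harmonic exactly.
#' This field is the analytic oracle used by the synthetic 4D-flow phantom
#' and by the pulsatile solver tests.
#'
#' @param r radial positions (m), `0 <= r <= R`.
#' @param t times (s).
#' @param harmonics complex flow harmonics `c_0..c_K` (m^3/s), as returned by
#'   [flow_harmonics()].
#' @param radius tube radius R (m).
#' @param nu kinematic viscosity (m^2/s).
#' @param period cycle length (s); defaults to the harmonics' attribute.
#' @return a numeric matrix `length(r) x length(t)` of axial velocities
#'   (m/s); dropped to a vector when `r` or `t` has length 1.
#' @examples
#' h <- c(1e-4 + 0i)  # steady 100 mL/s
#' attr(h, "period") <- 1
#' womersley_velocity(0, 0, h, radius = 0.01, nu = 3.3e-6)  # centreline 2*Q/(pi R^2)
#' @export
womersley_velocity <- function(r, t, harmonics, radius, nu,
                               period = attr(harmonics, "period")) {
  shapes <- womersley_radial_shapes(r, harmonics, radius, nu, period)
  u <- womersley_eval(shapes, t, period)
  if (length(r) == 1L || length(t) == 1L) drop(u) else u
}

# Per-harmonic complex radial shape functions U[k](r): u(r, t) =
# Re( sum_k U[k](r) exp(i k w t) ).  Returned as a length(r) x (K+1) complex
# matrix, reused by the phantom generator for efficiency.
womersley_radial_shapes <- function(r, harmonics, radius, nu, period) {
  if (any(r < -1e-12) || any(r > radius * (1 + 1e-9))) {
    stop_pahemo("Radial positions must satisfy 0 <= r <= R.")
  }
  if (radius <= 0 || nu <= 0 || period <= 0) {
    stop_pahemo("`radius`, `nu` and `period` must be positive.")
  }
  r <- pmin(pmax(r, 0), radius)
  k <- seq_along(harmonics) - 1L
  w <- 2 * pi / period
  shapes <- matrix(0 + 0i, nrow = length(r), ncol = length(harmonics))
  # steady harmonic: Poiseuille
  shapes[, 1] <- 2 * Re(harmonics[1]) / (pi * radius^2) * (1 - (r / radius)^2)
  for (j in seq_along(harmonics)[-1]) {
    qk <- harmonics[j]
    if (qk == 0) next
    alpha <- radius * sqrt(k[j] * w / nu)
    lam <- alpha * complex(modulus = 1, argument = 3 * pi / 4)  # i^(3/2) alpha
    j0l <- bessel_j0_complex(lam)
    denom <- 1 - 2 * bessel_j1_complex(lam) / (lam * j0l)
    shapes[, j] <- qk / (pi * radius^2) *
      (1 - bessel_j0_complex(lam * r / radius) / j0l) / denom
  }
  shapes
}

womersley_eval <- function(shapes, t, period) {
  w <- 2 * pi / period
  k <- seq_len(ncol(shapes)) - 1L
  ph <- exp(1i * outer(k, t) * w)          # (K+1) x length(t)
  Re(shapes %*% ph)
}

#' Analytic Womersley wall shear rate
#'
#' Signed wall velocity gradient `du/dr` at the wall of the Womersley field,
#' obtained from the closed-form Bessel derivative of each harmonic.  The
#' wall shear stress of a Newtonian fluid is `mu * |du/dr|`.
#'
#' @inheritParams womersley_velocity
#' @return numeric vector of `du/dr(R, t)` (1/s) at each `t`.
#' @export
womersley_wall_shear_rate <- function(t, harmonics, radius, nu,
                                      period = attr(harmonics, "period")) {
  if (radius <= 0 || nu <= 0 || period <= 0) {
    stop_pahemo("`radius`, `nu` and `period` must be positive.")
  }
  w <- 2 * pi / period
  k <- seq_along(harmonics) - 1L
  dshape <- complex(length(harmonics))
  dshape[1] <- -4 * Re(harmonics[1]) / (pi * radius^3)
  for (j in seq_along(harmonics)[-1]) {
    qk <- harmonics[j]
    if (qk == 0) next
    alpha <- radius * sqrt(k[j] * w / nu)
    lam <- alpha * complex(modulus = 1, argument = 3 * pi / 4)
    j0l <- bessel_j0_complex(lam)
    denom <- 1 - 2 * bessel_j1_complex(lam) / (lam * j0l)
    # d/dr [1 - J0(lam r/R)/J0(lam)] = (lam/R) J1(lam r/R)/J0(lam)
    dshape[j] <- qk / (pi * radius^2) *
      (lam / radius) * bessel_j1_complex(lam) / j0l / denom
  }
  ph <- exp(1i * outer(k, t) * w)
  as.numeric(Re(t(ph) %*% dshape))
}
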