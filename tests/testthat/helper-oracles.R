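# Shared fixtures and independent oracles for the test suite.
# Expensive objects (phantom studies, solver runs) are built lazily once per
# session and reused across test files.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env, inherits = FALSE)
}

# default P1-like phantom (period 0.95 s, SV 95 mL, RPA fraction 0.62) at
# clinical voxel spacing, noiseless
p1_spec <- function(...) phantom_spec(...)

p1_geometry <- function() cached("p1_geometry", {
  generate_bifurcation_geometry(p1_spec())
})

p1_study <- function() cached("p1_study", {
  generate_flow_study(p1_spec(), p1_geometry())
})

# --- independent oracles -------------------------------------------------

# numerical quadrature of an axisymmetric profile u(r): flow = int 2 pi r u dr
flux_quadrature <- function(u_of_r, radius, n = 4000L) {
  r <- seq(0, radius, length.out = n)
  u <- u_of_r(r)
  h <- r[2] - r[1]
  sum((head(2 * pi * r * u, -1) + tail(2 * pi * r * u, -1)) / 2) * h
}

# steady generalized-Newtonian pipe flow solved as a 1D boundary-value
# problem: the stress profile tau(r) = tau_w r/R is exact for any rheology,
# so invert mu(gdot) gdot = tau pointwise and integrate for the flow rate.
gn_steady_oracle <- function(flow, radius, rheo, n = 2000L) {
  gdot_of_tau <- function(tau) {
    vapply(tau, function(tt) {
      if (tt <= 0) return(0)
      stats::uniroot(function(g) quemada_viscosity(g, rheo) * g - tt,
                     c(1e-10, 1e7), tol = 1e-13)$root
    }, numeric(1))
  }
  flow_of_tauw <- function(tw) {
    r <- seq(0, radius, length.out = n)
    g <- gdot_of_tau(tw * r / radius)
    h <- r[2] - r[1]
    # u(r) = int_r^R gdot ds (trapezoid), then Q = int 2 pi r u dr
    u <- rev(cumsum(rev((c(g[-1], 0) + g) / 2))) * h
    sum((head(2 * pi * r * u, -1) + tail(2 * pi * r * u, -1)) / 2) * h
  }
  stats::uniroot(function(tw) flow_of_tauw(tw) - flow,
                 c(1e-6, 1e3), tol = 1e-10)$root
}

# --- cached solver runs --------------------------------------------------

steady_newtonian_run <- function() cached("steady_newtonian_run", {
  wf <- flow_waveform(seq(0, 0.8, length.out = 65)[1:64], rep(1e-4, 64), 0.8)
  suppressWarnings(simulate_pulsatile_tube(
    radius = 0.01, length = 0.06, inlet = wf,
    rheology = newtonian_params(3.5e-3),
    outlet = windkessel_params(1e7, 5e7, 1e-8),
    config = solver_config(nr = 32, nz = 16, n_cycles_max = 8)
  ))
})

womersley_run <- function() cached("womersley_run", {
  T <- 0.8
  tt <- seq(0, T, length.out = 65)[1:64]
  wf <- flow_waveform(tt, pi * 0.01^2 * (0.15 + 0.12 * cos(2 * pi * tt / T)), T)
  suppressWarnings(simulate_pulsatile_tube(
    radius = 0.01, length = 0.05, inlet = wf,
    rheology = newtonian_params(3.5e-3),
    outlet = windkessel_params(1e7, 8e7, 1e-8),
    config = solver_config(nr = 32, nz = 16, n_cycles_max = 10)
  ))
})

womersley_waveform <- function() {
  T <- 0.8
  tt <- seq(0, T, length.out = 65)[1:64]
  flow_waveform(tt, pi * 0.01^2 * (0.15 + 0.12 * cos(2 * pi * tt / T)), T)
}

quemada_steady_run <- function() cached("quemada_steady_run", {
  wf <- flow_waveform(seq(0, 0.8, length.out = 65)[1:64], rep(6e-5, 64), 0.8)
  suppressWarnings(simulate_pulsatile_tube(
    radius = 0.01, length = 0.06, inlet = wf,
    rheology = rheology_params(),
    outlet = windkessel_params(1e7, 5e7, 1e-8),
    config = solver_config(nr = 32, nz = 16, n_cycles_max = 8)
  ))
})

l2_rel <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))
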