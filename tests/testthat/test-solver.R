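test_that("flow regime assessment applies the 150-alpha criterion", {
  r <- assess_flow_regime(0.2, 0.03, 1060, 3.5e-3, 0.8)
  expect_equal(r$re_peak, 1060 * 0.2 * 0.03 / 3.5e-3)
  expect_equal(r$re_peak, 1817, tolerance = 1e-3)
  expect_equal(r$alpha, 23.1, tolerance = 1e-2)
  expect_equal(r$critical, 150 * r$alpha)
  expect_true(r$laminar)
  # zero velocity is always laminar
  expect_true(assess_flow_regime(0, 0.03, 1060, 3.5e-3, 0.8)$laminar)
  # doubling the viscosity halves Re and divides alpha by sqrt(2)
  r2 <- assess_flow_regime(0.2, 0.03, 1060, 7e-3, 0.8)
  expect_equal(r2$re_peak, r$re_peak / 2)
  expect_equal(r2$alpha, r$alpha / sqrt(2))
  expect_equal((r$re_peak / r$critical) / (r2$re_peak / r2$critical),
               sqrt(2), tolerance = 1e-12)
})

test_that("steady Newtonian flow reproduces Poiseuille and the 3EWK level", {
  run <- steady_newtonian_run()
  f <- converged_final_cycle(run)
  R <- 0.01; Q <- 1e-4; mu <- 3.5e-3
  nt <- length(f$times); zmid <- length(f$z_centers) %/% 2
  w_an <- 2 * Q / (pi * R^2) * (1 - (f$r_centers / R)^2)
  expect_lt(l2_rel(f$w[, zmid, nt], w_an), 0.02)
  expect_equal(tail(f$p_out, 1), (1e7 + 5e7) * Q, tolerance = 0.005)
  # WSS = 4 mu Q / (pi R^3) = 0.4456 Pa
  ws <- wall_shear_stress(f)
  expect_equal(ws$wss[zmid, nt], 4 * mu * Q / (pi * R^3), tolerance = 0.03)
  expect_equal(4 * mu * Q / (pi * R^3), 0.4456, tolerance = 1e-4)
})

test_that("single-harmonic flow matches the Womersley solution at default grid", {
  run <- womersley_run()
  f <- converged_final_cycle(run)
  wf <- womersley_waveform()
  h <- flow_harmonics(wf, 10)
  nu <- 3.5e-3 / 1060
  zmid <- length(f$z_centers) %/% 2
  u_an <- womersley_velocity(f$r_centers, f$times %% 0.8, h, 0.01, nu, 0.8)
  expect_lt(l2_rel(f$w[, zmid, ], u_an), 0.05)
  gd_an <- -womersley_wall_shear_rate(f$times %% 0.8, h, 0.01, nu, 0.8)
  expect_lt(l2_rel(f$wall_shear[zmid, ], gd_an), 0.05)
})

test_that("mass is conserved instantaneously through every cross-section", {
  f <- converged_final_cycle(womersley_run())
  dr <- diff(f$r_centers[1:2])
  q_ref <- max(abs(vapply(seq_along(f$times), function(k) {
    sum(2 * pi * f$r_centers * f$w[, 1, k]) * dr
  }, numeric(1))))
  worst <- 0
  for (k in seq_along(f$times)) {
    fluxes <- colSums(2 * pi * f$r_centers * f$w[, , k]) * dr
    worst <- max(worst, (max(fluxes) - min(fluxes)) / q_ref)
  }
  expect_lt(worst, 0.005)
  expect_lt(f$max_divergence, 1e-6)
})

test_that("no-slip holds at the wall and the divergence residual is tiny", {
  f <- converged_final_cycle(steady_newtonian_run())
  # wall ghost condition: extrapolated wall velocity from the last two cells
  nr <- length(f$r_centers)
  wall_u <- 1.5 * f$w[nr, , dim(f$w)[3]] - 0.5 * f$w[nr - 1, , dim(f$w)[3]]
  expect_lt(max(abs(wall_u)), 0.05 * max(abs(f$w)))
})

test_that("steady Quemada WSS matches the 1D generalized-Newtonian oracle", {
  run <- quemada_steady_run()
  f <- converged_final_cycle(run)
  tau_w <- gn_steady_oracle(6e-5, 0.01, rheology_params())
  ws <- wall_shear_stress(f)
  zmid <- length(f$z_centers) %/% 2
  expect_equal(ws$wss[zmid, dim(ws$wss)[2]], tau_w, tolerance = 0.03)
})

test_that("periodicity log decays geometrically and convergence is enforced", {
  run <- steady_newtonian_run()
  met <- run$cycle_log$periodicity_pct
  expect_true(all(diff(log(met)) < 0))
  f <- converged_final_cycle(run)
  expect_lt(f$periodicity_pct, run$config$periodicity_tol)
  # a slowly-relaxing outlet cannot converge in three cycles
  wf <- flow_waveform(seq(0, 0.8, length.out = 65)[1:64], rep(1e-4, 64), 0.8)
  slow <- suppressWarnings(simulate_pulsatile_tube(
    0.01, 0.06, wf, newtonian_params(3.5e-3),
    windkessel_params(1e7, 5e8, 8e-9),  # tau = 4 s
    solver_config(nr = 16, nz = 8, n_cycles_max = 3)
  ))
  expect_error(converged_final_cycle(slow), class = "pahemo_convergence_error")
})

test_that("halving the radial cell size reduces the Womersley error", {
  coarse <- cached("womersley_coarse_run", {
    wf <- womersley_waveform()
    suppressWarnings(simulate_pulsatile_tube(
      0.01, 0.05, wf, newtonian_params(3.5e-3),
      windkessel_params(1e7, 8e7, 1e-8),
      solver_config(nr = 16, nz = 16, n_cycles_max = 10)
    ))
  })
  wf <- womersley_waveform()
  h <- flow_harmonics(wf, 10)
  nu <- 3.5e-3 / 1060
  err_of <- function(run) {
    f <- converged_final_cycle(run)
    zmid <- length(f$z_centers) %/% 2
    u_an <- womersley_velocity(f$r_centers, f$times %% 0.8, h, 0.01, nu, 0.8)
    l2_rel(f$w[, zmid, ], u_an)
  }
  expect_lt(err_of(womersley_run()), err_of(coarse) / 2)
})
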