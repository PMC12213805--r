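test_that("degenerate spec without branches voxelises to a single all-MPA cylinder", {
  spec <- phantom_spec(branch_radii = c(lpa = 0.0175, rpa = 0),
                       branch_angles = c(lpa = 0, rpa = 0))
  geo <- generate_bifurcation_geometry(spec)
  expect_true(all(geo$labels[geo$mask] == 1L))
  # every occupied slice is a full circle of the MPA radius
  areas <- apply(geo$mask, 3, sum) * prod(geo$spacing[1:2])
  occ <- areas > 0
  expect_lt(max(abs(areas[occ] - pi * 17.5^2)) / (pi * 17.5^2), 0.15)
})

test_that("voxelised MPA cross-section area matches the analytic circle", {
  spec <- phantom_spec(mpa_radius = 0.015)
  geo <- generate_bifurcation_geometry(spec, spacing = c(2.5, 2.5, 2.5))
  # voxel-count area of a mid-MPA slice vs pi r^2
  k <- round((25 - geo$origin[3]) / geo$spacing[3]) + 1L
  area <- sum(geo$labels[, , k] == 1L) * geo$spacing[1] * geo$spacing[2]
  expect_lt(abs(area - pi * 15^2) / (pi * 15^2), 0.10)
})

test_that("region labels partition the vessel mask", {
  geo <- p1_geometry()
  expect_true(all((geo$labels > 0L) == geo$mask))
  expect_true(all(geo$labels[!geo$mask] == 0L))
  expect_setequal(unique(as.integer(geo$labels[geo$mask])), c(1L, 2L, 3L))
})

test_that("under-resolved spacing is rejected", {
  expect_error(
    generate_bifurcation_geometry(phantom_spec(), spacing = c(8, 8, 8)),
    class = "pahemo_resolution_error"
  )
})

test_that("Womersley velocity reduces to Poiseuille for steady harmonics", {
  h <- structure(c(1e-4 + 0i), period = 1)
  R <- 0.01
  r <- seq(0, R, length.out = 11)
  u <- womersley_velocity(r, 0, h, R, nu = 3.3e-6)
  expect_equal(u, 2e-4 / (pi * R^2) * (1 - (r / R)^2), tolerance = 1e-12)
})

test_that("Womersley field satisfies no-slip and recovers the prescribed flow", {
  wf <- half_sine_waveform(95, 0.95)
  h <- flow_harmonics(wf, 10)
  R <- 0.0175
  nu <- 4.4e-6
  tt <- seq(0, 0.95, length.out = 7)[1:6]
  expect_lt(max(abs(womersley_velocity(R, tt, h, R, nu))), 1e-10)
  for (t in tt) {
    q_quad <- flux_quadrature(function(r) womersley_velocity(r, t, h, R, nu), R)
    q_presc <- harmonics_flow(h, t)
    expect_lt(abs(q_quad - q_presc), 0.005 * max(abs(wf$flow)))
  }
})

test_that("noiseless fine-spacing study recovers the stroke volume within 2%", {
  spec <- p1_spec()
  geo <- generate_bifurcation_geometry(spec, spacing = c(1.5, 1.5, 1.5))
  study <- generate_flow_study(spec, geo, spacing = c(1.5, 1.5, 1.5))
  sv <- stroke_volume(flow_waveform(extract_inlet_profile(study, geo)))
  expect_lt(abs(sv - 95) / 95, 0.02)
})

test_that("seeded study generation is reproducible bit for bit", {
  spec <- phantom_spec(noise_sd = 0.05, seed = 42L)
  geo <- p1_geometry()
  s1 <- generate_flow_study(spec, geo)
  s2 <- generate_flow_study(spec, geo)
  expect_identical(s1$velocity, s2$velocity)
  expect_identical(s1$magnitude, s2$magnitude)
})

test_that("velocities never exceed the encoding limit, and aliasing specs fail", {
  spec <- phantom_spec(noise_sd = 0.3, seed = 7L)
  study <- generate_flow_study(spec, p1_geometry())
  for (v in study$velocity) expect_lte(max(abs(v)), spec$venc)
  fast <- phantom_spec(stroke_volume_ml = 400, period = 0.6)
  expect_error(generate_flow_study(fast), class = "pahemo_venc_error")
})

test_that("P1-like study yields the prescribed RPA flow split downstream", {
  split <- branch_split(p1_study(), p1_geometry())
  expect_equal(split$fraction_rpa, 0.62, tolerance = 0.02 / 0.62)
})

test_that("printed cohort fixture matches the published values", {
  ch <- printed_cohort()
  expect_equal(nrow(ch), 7L)
  expect_equal(ch$stroke_volume_ml[ch$patient == "P1"], 95)
  expect_equal(ch$tawss_whole_pa[ch$patient == "P3"], 3.62)
  expect_equal(ch$rpa_fraction_4dflow[ch$patient == "P7"], 0.69)
  expect_true(all(abs(ch$rpa_fraction_4dflow + ch$lpa_fraction_4dflow - 1) <= 0.01))
  expect_true(all(vapply(ch[-1], function(x) all(x > 0), logical(1))))
})
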