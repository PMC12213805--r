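test_that("inlet profile is lumen-shaped and integrates to the phantom waveform", {
  geo <- p1_geometry()
  study <- p1_study()
  prof <- extract_inlet_profile(study, geo)
  # centre sample larger than edge samples at peak systole
  ctr <- sqrt(rowSums(sweep(prof$points[, 1:2], 2,
                            colMeans(prof$points[, 1:2]))^2))
  qf <- colSums(prof$velocity) * prof$area_mm2
  fpk <- which.max(abs(qf))
  expect_gt(prof$velocity[which.min(ctr), fpk],
            max(prof$velocity[ctr > 0.9 * max(ctr), fpk]))
  # per-frame plane flux vs the prescribed waveform (3%)
  q_true <- harmonics_flow(pahemo:::phantom_harmonics(p1_spec())$mpa,
                           study$frame_times)
  q_meas <- qf * 1e-6
  expect_lt(max(abs(q_meas - q_true)) / max(abs(q_true)), 0.03)
})

test_that("flipping the plane normal negates the through-plane profile", {
  geo <- p1_geometry()
  study <- p1_study()
  pl <- geo$inlet_plane
  flipped <- analysis_plane(pl$origin, -pl$normal)
  a <- extract_inlet_profile(study, geo, pl)
  b <- extract_inlet_profile(study, geo, flipped)
  expect_equal(colSums(a$velocity), -colSums(b$velocity), tolerance = 1e-10)
})

test_that("uniform-velocity profile gives Q = v * A and zeros stay zero", {
  prof <- structure(
    list(points = cbind(runif(707), runif(707), 0), area_mm2 = 1,
         velocity = matrix(0.1, 707, 12),
         frame_times = seq(0, 0.95, length.out = 13)[1:12], period = 0.95),
    class = "inlet_profile"
  )
  wf <- flow_waveform(prof)
  expect_equal(wf$flow[1], 7.07e-5, tolerance = 1e-12)
  prof$velocity[] <- 0
  expect_true(all(flow_waveform(prof)$flow == 0))
})

test_that("stroke volume integrates waveforms correctly", {
  # constant 100 mL/s over 0.95 s (P1's printed SV/period pair)
  wf <- flow_waveform(seq(0, 0.95, length.out = 20)[1:19], rep(1e-4, 19), 0.95)
  expect_equal(stroke_volume(wf), 95, tolerance = 1e-10)
  # half-sine lobe: SV = 2 A T / (3 pi)
  A <- 5e-4; T <- 0.9
  ts <- T / 3
  t <- seq(0, T, length.out = 2001)[1:2000]
  wf2 <- flow_waveform(t, ifelse(t < ts, A * sin(pi * t / ts), 0), T)
  expect_equal(stroke_volume(wf2) * 1e-6, 2 * A * T / (3 * pi), tolerance = 1e-5)
  # a regurgitant lobe reduces the signed integral
  wf3 <- flow_waveform(t, ifelse(t < ts, A * sin(pi * t / ts), 0) -
                         ifelse(t >= ts & t < 2 * ts, 0.2 * A * sin(pi * (t - ts) / ts), 0), T)
  expect_equal(stroke_volume(wf3), 0.8 * stroke_volume(wf2), tolerance = 1e-6)
})

test_that("branch fractions are normalised and symmetric phantoms split 50/50", {
  split <- branch_split(p1_study(), p1_geometry())
  expect_equal(split$fraction_rpa + split$fraction_lpa, 1)
  sym <- phantom_spec(branch_radii = c(lpa = 0.011, rpa = 0.011),
                      branch_angles = c(lpa = 42, rpa = 42),
                      rpa_fraction = 0.5)
  gs <- generate_bifurcation_geometry(sym)
  ss <- generate_flow_study(sym, gs)
  sp <- branch_split(ss, gs)
  expect_equal(sp$fraction_rpa, 0.5, tolerance = 0.01 / 0.5)
})

test_that("plane-mean peak-systolic velocity matches the analytic field", {
  geo <- p1_geometry()
  study <- p1_study()
  v <- mean_peak_systolic_velocity(study, geo)
  # independent value: lumen mean of |u| at the frame of peak analytic flow
  spec <- p1_spec()
  h <- pahemo:::phantom_harmonics(spec)$mpa
  q <- harmonics_flow(h, study$frame_times)
  tpk <- study$frame_times[which.max(abs(q))]
  r <- seq(0, spec$mpa_radius, length.out = 2000)
  u <- womersley_velocity(r, tpk, h, spec$mpa_radius, spec$nu)
  v_true <- sum(2 * pi * r * abs(u)) / sum(2 * pi * r)
  expect_equal(v, v_true, tolerance = 0.10)
})

test_that("flow quantities are linear in the velocity field", {
  geo <- p1_geometry()
  study <- p1_study()
  scaled <- study
  for (nm in names(scaled$velocity)) {
    scaled$velocity[[nm]] <- scaled$velocity[[nm]] * 0.5
  }
  wf1 <- flow_waveform(extract_inlet_profile(study, geo))
  wf2 <- flow_waveform(extract_inlet_profile(scaled, geo))
  expect_equal(wf2$flow, 0.5 * wf1$flow, tolerance = 1e-12)
  expect_equal(stroke_volume(wf2), 0.5 * stroke_volume(wf1), tolerance = 1e-12)
  s1 <- branch_split(study, geo)
  s2 <- branch_split(scaled, geo)
  expect_equal(s1$fraction_rpa, s2$fraction_rpa, tolerance = 1e-12)
})

test_that("refining the in-plane grid converges the flow estimate", {
  geo <- p1_geometry()
  study <- p1_study()
  q_at <- function(h) {
    mean(flow_waveform(extract_inlet_profile(study, geo, grid_spacing = h))$flow)
  }
  q2 <- q_at(2); q1 <- q_at(1); q05 <- q_at(0.5)
  expect_lt(abs(q05 - q1), abs(q05 - q2) + 1e-12)
})
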