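make_series <- function(wss, times, period, area = NULL) {
  structure(
    list(wss = wss, times = times, period = period,
         area = if (is.null(area)) rep(1, nrow(wss)) else area,
         region = rep("mpa", nrow(wss)), z = seq_len(nrow(wss))),
    class = "wss_series"
  )
}

test_that("TAWSS averages constants, rectifies sines and ignores the time origin", {
  t <- seq(0, 1, length.out = 65)[1:64]
  # constant 1.62 Pa (the P1 whole-geometry level) stays 1.62
  s_const <- make_series(matrix(1.62, 3, 64), t, 1)
  expect_equal(tawss(s_const)$tawss_pa, rep(1.62, 3), tolerance = 1e-12)
  # A sin(wt) -> 2A/pi
  A <- 2.5
  s_sin <- make_series(matrix(A * sin(2 * pi * t), 1, 64, byrow = TRUE), t, 1)
  expect_equal(tawss(s_sin)$tawss_pa, 2 * A / pi, tolerance = 1e-3)
  # time-origin shift leaves TAWSS unchanged
  shift <- 17
  s_shift <- make_series(matrix(A * sin(2 * pi * c(t[-(1:shift)], t[1:shift] + 1)),
                                1, 64, byrow = TRUE), t, 1)
  expect_equal(tawss(s_shift)$tawss_pa, tawss(s_sin)$tawss_pa, tolerance = 1e-9)
  # incomplete cycles are rejected
  s_bad <- make_series(matrix(1, 1, 32), t[1:32], 1)
  expect_error(tawss(s_bad))
})

test_that("zero flow gives zero WSS and Womersley WSS follows the oracle", {
  f <- converged_final_cycle(steady_newtonian_run())
  f0 <- f
  f0$wall_shear[] <- 0
  expect_true(all(wall_shear_stress(f0)$wss == 0))
  f <- converged_final_cycle(womersley_run())
  ws <- wall_shear_stress(f)
  h <- flow_harmonics(womersley_waveform(), 10)
  gd_an <- -womersley_wall_shear_rate(f$times %% 0.8, h, 0.01, 3.5e-3 / 1060, 0.8)
  zmid <- length(f$z_centers) %/% 2
  expect_lt(l2_rel(ws$wss[zmid, ], 3.5e-3 * gd_an), 0.05)
})

test_that("regional averages weight by area and respect region sets", {
  map <- tibble::tibble(
    location = 1:4,
    region = c("mpa", "mpa", "lpa", "rpa"),
    area = c(1, 1, 1, 1),
    tawss_pa = c(1, 1, 2, 2)
  )
  expect_equal(regional_average(map, "mpa"), 1.0)
  expect_equal(regional_average(map), 1.5)
  expect_equal(regional_average(map, c("lpa", "rpa")), 2.0)
  map$area <- c(3, 1, 2, 2)
  expect_equal(regional_average(map, "mpa"), 1.0)
  expect_error(regional_average(map, "aorta"))
})

test_that("printed whole-geometry TAWSS always exceeds the MPA-only value", {
  ch <- printed_cohort()
  expect_true(all(ch$tawss_whole_pa >= ch$tawss_mpa_pa))
})

test_that("a linear shear layer is recovered exactly at any voxel size", {
  spec <- phantom_spec(branch_radii = c(lpa = 0.0175, rpa = 0),
                       branch_angles = c(lpa = 0, rpa = 0),
                       stroke_volume_ml = 60)
  geo <- generate_bifurcation_geometry(spec, c(2.5, 2.5, 2.5))
  study <- generate_flow_study(spec, geo, spacing = c(2.5, 2.5, 2.5))
  # overwrite the axial velocity with a pure linear profile in wall distance
  gamma <- 25  # 1/s
  d <- dim(geo$mask); sp <- geo$spacing / 1000
  coords <- lapply(1:3, function(a) geo$origin[a] / 1000 + (seq_len(d[a]) - 1) * sp[a])
  grid <- as.matrix(expand.grid(coords[[1]], coords[[2]], coords[[3]]))
  co <- pahemo:::limb_coords(grid, geo$meta$limbs$mpa)
  vz <- pmax(spec$mpa_radius - co$rho, 0) * gamma
  nf <- length(study$frame_times)
  study$velocity$vz <- array(rep(vz * as.numeric(geo$mask), nf), c(d, nf))
  study$velocity$vx[] <- 0
  study$velocity$vy[] <- 0
  est <- voxel_wss_estimate(study, geo, fit_depth = 2L)
  mu_ref <- unname(viscosity_bounds()["mu_inf"])
  expect_equal(unique(round(est$tawss_pa, 10)), round(mu_ref * gamma, 10))
})

test_that("single-voxel fits underestimate a parabolic gradient by 1 - d/(2R)", {
  # closed form: for u(x) = g x (1 - x/(2R)), the zero-intercept slope
  # through a sample at depth d is g (1 - d/(2R))
  g <- 30; R <- 0.0175
  d <- c(0.001, 0.002, 0.004)
  u <- g * d * (1 - d / (2 * R))
  expect_equal(u / d, g * (1 - d / (2 * R)), tolerance = 1e-12)
})

test_that("voxel-grade TAWSS sits below the analytic value and worsens with voxel size", {
  spec <- p1_spec()
  fine <- phantom_wall_tawss(spec)
  coarse_at <- function(h) {
    geo <- generate_bifurcation_geometry(spec, rep(h, 3))
    st <- generate_flow_study(spec, geo, spacing = rep(h, 3))
    regional_average(voxel_wss_estimate(st, geo))
  }
  c25 <- coarse_at(2.5)
  c50 <- coarse_at(5)
  f <- mean(fine$tawss_pa)
  expect_lt(c25, f)
  b25 <- resolution_bias(f, c25)
  b50 <- resolution_bias(f, c50)
  expect_true(b25$ratio > b50$ratio)
  expect_true(b25$ratio > 0 && b25$ratio < 1)
  expect_equal(b25$gap, f - c25)
})

test_that("resolution bias handles edge cases and the printed plane gap", {
  eq <- resolution_bias(1.5, 1.5)
  expect_equal(eq$ratio, 1)
  expect_equal(eq$gap, 0)
  expect_true(is.na(resolution_bias(0, 0.1)$ratio))
  t4 <- printed_plane_tawss()
  mpa <- t4[t4$region == "MPA", ]
  expect_equal(resolution_bias(mpa$cfd_mean_pa, mpa$flow4d_mean_pa)$ratio,
               0.064, tolerance = 1e-2)
  expect_true(all(t4$flow4d_mean_pa < t4$cfd_mean_pa))
})
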