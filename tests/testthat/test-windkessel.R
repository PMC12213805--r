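test_that("tuning recovers total resistance and compliance from targets", {
  # P1 RPA back-computation: 5115 Pa at 6.2e-5 m^3/s -> R_total = 8.25e7
  wk <- tune_3ewk(5115, 6.2e-5, proximal_fraction = 1.15 / 82.5,
                  time_constant = 0.647)
  expect_equal(wk$r1 + wk$r2, 5115 / 6.2e-5, tolerance = 1e-12)
  expect_equal(wk$r1 + wk$r2, 8.25e7, tolerance = 1e-4)
  # C = tau / R2; with tau = 0.647 s and R2 = 7.10e7 this matches the
  # printed P1 RPA compliance 9.12e-9 to 3 significant figures
  wk2 <- tune_3ewk(5115, 6.2e-5, proximal_fraction = 1 - 7.10e7 / 8.25e7,
                   time_constant = 0.647)
  expect_equal(wk2$r2, 7.10e7, tolerance = 1e-6)
  expect_equal(signif(wk2$c, 3), 9.11e-9)
  # boundary: f = 0 puts everything distal
  wk0 <- tune_3ewk(5000, 5e-5, proximal_fraction = 0)
  expect_equal(wk0$r1, 0)
  expect_equal(wk0$r2, 1e8)
  expect_error(tune_3ewk(5000, 0))
})

test_that("constant flow converges to the closed-form (R1+R2) Q level", {
  wk <- windkessel_params(1.15e7, 0.71e8, 9.12e-9)
  wf <- flow_waveform(seq(0, 0.95, length.out = 65)[1:64], rep(6.2e-5, 64), 0.95)
  pw <- simulate_3ewk(wk, wf, n_cycles = 8)
  mp <- mean_pressure(pw)
  expect_equal(mp$pressure_pa, (1.15e7 + 0.71e8) * 6.2e-5, tolerance = 0.005)
  expect_equal(mp$pressure_mmhg, 38.4, tolerance = 0.005)
})

test_that("cycle-mean pressure of a periodic drive equals (R1+R2) Qbar", {
  wk <- windkessel_params(8e6, 9e7, 8e-9)
  wf <- half_sine_waveform(80, 0.8)
  pw <- simulate_3ewk(wk, wf, n_cycles = 12)
  mp <- mean_pressure(pw)
  expect_equal(mp$pressure_pa, (wk$r1 + wk$r2) * mean(wf$flow),
               tolerance = 0.005)
})

test_that("pressure response is linear in the driving flow", {
  wk <- windkessel_params(1e7, 1e8, 7e-9)
  wf <- half_sine_waveform(60, 0.75)
  wf2 <- flow_waveform(wf$time, 2 * wf$flow, 0.75)
  p1 <- simulate_3ewk(wk, wf, n_cycles = 12)
  p2 <- simulate_3ewk(wk, wf2, n_cycles = 12)
  last <- p1$cycle == max(p1$cycle)
  expect_equal(p2$pressure[last], 2 * p1$pressure[last], tolerance = 1e-3)
})

test_that("periodicity metric measures cycle-to-cycle variation", {
  a <- sin(seq(0, 2 * pi, length.out = 100))
  expect_equal(periodicity_metric(a, a), 0)
  expect_equal(periodicity_metric(1.01 * a, a), 1, tolerance = 1e-10)
  expect_equal(periodicity_metric(a, 1.01 * a), 100 * 0.01 / 1.01,
               tolerance = 1e-10)
  expect_error(periodicity_metric(a, a * 0))
  expect_error(periodicity_metric(a, a[1:50]))
})

test_that("startup transient decays geometrically at rate exp(-T/tau)", {
  qbar <- mean(half_sine_waveform(80, 0.75)$flow)
  wk <- tune_3ewk(mmhg_to_pa(40), qbar, time_constant = 0.7)
  wf <- half_sine_waveform(80, 0.75)
  pw <- simulate_3ewk(wk, wf, n_cycles = 7, pc0 = 0)
  n_per <- sum(pw$cycle == 1)
  met <- vapply(2:6, function(cyc) {
    a <- pw$pressure[((cyc - 1) * n_per + 1):(cyc * n_per)]
    b <- pw$pressure[(cyc * n_per + 1):((cyc + 1) * n_per)]
    periodicity_metric(a, b)
  }, numeric(1))
  ratios <- met[-1] / met[-length(met)]
  expect_true(all(ratios < 0.5))              # geometric decay
  expect_equal(mean(ratios), exp(-0.75 / 0.7), tolerance = 0.1)
  expect_lt(met[4], 1)                        # below 1% by cycle 5-6
})

test_that("tune -> simulate round trip hits the target mean pressure within 1%", {
  for (sv in c(41, 95, 184)) {
    wf <- half_sine_waveform(sv, 0.8)
    tuned <- tune_3ewk(mmhg_to_pa(44), mean(wf$flow))
    mp <- mean_pressure(simulate_3ewk(tuned, wf, n_cycles = 10))
    expect_equal(mp$pressure_mmhg, 44, tolerance = 0.01)
  }
})

test_that("mean_pressure handles constants, zeros and pure oscillations", {
  wk <- windkessel_params(1e7, 1e8, 7e-9)
  wf <- half_sine_waveform(60, 0.8)
  pw <- simulate_3ewk(wk, wf, n_cycles = 4)
  pw$pressure[] <- 5115
  expect_equal(mean_pressure(pw)$pressure_mmhg, 38.37, tolerance = 2e-4)
  pw$pressure[] <- 0
  expect_equal(mean_pressure(pw)$pressure_pa, 0)
  pw$pressure <- 2000 + sin(2 * pi * pw$time / 0.8)
  expect_equal(mean_pressure(pw)$pressure_pa, 2000, tolerance = 1e-6)
})

test_that("printed Windkessel time constants all lie in 0.59-0.73 s", {
  ch <- printed_cohort()
  tau <- c(ch$r2_rpa_pa_s_m3 * ch$c_rpa_m3_pa, ch$r2_lpa_pa_s_m3 * ch$c_lpa_m3_pa)
  expect_length(tau, 14L)
  expect_true(all(tau >= 0.59 & tau <= 0.73))
})
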