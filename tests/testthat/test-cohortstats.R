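test_that("collinear points give a perfect fit and degenerate input fails", {
  df <- tibble::tibble(x = 1:5, y = 2 - 3 * (1:5))
  f <- suppressWarnings(linear_fit(df, x, y))  # perfect fit warns in summary.lm
  expect_equal(f$r_squared, 1)
  expect_equal(f$slope, -3)
  expect_error(linear_fit(tibble::tibble(x = rep(1, 5), y = 1:5), x, y))
  expect_error(linear_fit(tibble::tibble(x = 1:2, y = 1:2), x, y))
})

test_that("printed cohort reproduces the TAWSS-pressure correlations", {
  ch <- printed_cohort()
  whole <- linear_fit(ch, tawss_whole_pa, mean_pap_mmhg)
  expect_equal(round(whole$r_squared, 2), 0.84)
  expect_lt(whole$slope, 0)
  # R^2 equals the squared Pearson correlation
  expect_equal(whole$r_squared,
               cor(ch$tawss_whole_pa, ch$mean_pap_mmhg)^2, tolerance = 1e-12)
  mpa <- linear_fit(ch, tawss_mpa_pa, mean_pap_mmhg)
  expect_equal(mpa$r_squared, cor(ch$tawss_mpa_pa, ch$mean_pap_mmhg)^2,
               tolerance = 1e-12)
  expect_lt(mpa$slope, 0)
  expect_lt(mpa$r_squared, whole$r_squared)
})

test_that("R^2 is invariant to affine rescaling of either variable", {
  ch <- printed_cohort()
  base <- linear_fit(ch, tawss_whole_pa, mean_pap_mmhg)$r_squared
  ch2 <- dplyr::mutate(ch,
                       tawss_whole_pa = 3.7 * .data$tawss_whole_pa - 1,
                       mean_pap_mmhg = 0.5 * .data$mean_pap_mmhg + 10)
  expect_equal(linear_fit(ch2, tawss_whole_pa, mean_pap_mmhg)$r_squared, base,
               tolerance = 1e-12)
})

test_that("tidy and glance expose broom-style summaries", {
  f <- linear_fit(printed_cohort(), tawss_whole_pa, mean_pap_mmhg)
  td <- tidy(f)
  expect_equal(td$term, c("(Intercept)", "tawss_whole_pa"))
  expect_equal(td$estimate[2], f$slope)
  gl <- glance(f)
  expect_equal(gl$r.squared, f$r_squared)
  expect_equal(gl$nobs, 7L)
})

test_that("validation metrics recompute the printed CFD/4D-flow agreement", {
  rep <- validation_metrics()
  expect_equal(nrow(rep), 7L)
  expect_true(all(rep$velocity_diff_pct >= 0))
  g <- glance(rep)
  expect_equal(round(g$max_velocity_diff_pct), 19)
  expect_equal(rep$patient[which.max(rep$velocity_diff_pct)], "P4")
  expect_lte(g$max_rpa_fraction_diff, 0.035)
  expect_equal(g$mean_velocity_diff_pct, 10.4, tolerance = 0.01)
  # identical columns give all-zero differences
  same <- printed_cohort()
  same$mpa_velocity_cfd_ms <- same$mpa_velocity_4dflow_ms
  same$rpa_fraction_cfd <- same$rpa_fraction_4dflow
  z <- validation_metrics(same)
  expect_true(all(z$velocity_diff_pct == 0 & z$rpa_fraction_diff == 0))
})

test_that("noiseless synthetic cohorts are recovered perfectly", {
  ch <- generate_synthetic_cohort(n = 50, slope = -8, intercept = 60,
                                  noise_sd = 0, seed = 3L)
  f <- suppressWarnings(linear_fit(ch, tawss_whole_pa, mean_pap_mmhg))
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_equal(f$slope, -8, tolerance = 1e-10)
})

test_that("the fitted slope lands within 3 standard errors of the truth", {
  ch <- generate_synthetic_cohort(n = 200, slope = -11.6, intercept = 68.2,
                                  noise_sd = 5, seed = 11L)
  f <- linear_fit(ch, tawss_whole_pa, mean_pap_mmhg)
  se <- tidy(f)$std.error[2]
  expect_lt(abs(f$slope - (-11.6)), 3 * se)
  expect_lt(f$slope, 0)
})

test_that("correlation reports fit present predictors and skip absent ones", {
  ch <- printed_cohort()
  rep <- suppressMessages(
    cohort_correlation_report(ch, predictors = c("tawss_whole_pa", "diameter_mm"))
  )
  expect_equal(rep$predictor, "tawss_whole_pa")
  expect_equal(attr(rep, "skipped"), "diameter_mm")
  full <- cohort_correlation_report(ch)
  expect_equal(round(full$r_squared[full$predictor == "tawss_whole_pa"], 2), 0.84)
  expect_true(all(full$n == 7))
})

test_that("fixture-mode pipeline reproduces the cohort analyses and writes outputs", {
  out <- withr::local_tempdir()
  res <- run_pipeline(pipeline_config(mode = "fixture", out_dir = out))
  expect_equal(round(res$correlations$r_squared[
    res$correlations$predictor == "tawss_whole_pa"], 2), 0.84)
  expect_true(file.exists(file.path(out, "cohort.csv")))
  expect_true(file.exists(file.path(out, "regressions.json")))
  expect_true(file.exists(file.path(out, "pipeline.log")))
  js <- jsonlite::read_json(file.path(out, "regressions.json"),
                            simplifyVector = TRUE)
  expect_true("tawss_whole_pa" %in% js$predictor)
})

test_that("phantom-mode pipeline is deterministic under a fixed seed", {
  spec <- phantom_spec(stroke_volume_ml = 76, period = 0.64,
                       rpa_fraction = 0.52, noise_sd = 0.02, seed = 5L)
  run_once <- function(dir) {
    run_pipeline(pipeline_config(
      mode = "phantom", out_dir = dir, specs = list(P6 = spec),
      spacing = c(2.5, 2.5, 2.5)
    ))
  }
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- run_once(d1); r2 <- run_once(d2)
  expect_identical(readLines(file.path(d1, "cohort.csv")),
                   readLines(file.path(d2, "cohort.csv")))
  expect_equal(r1$cohort$stroke_volume_ml, 76, tolerance = 0.02)
  expect_equal(r1$cohort$rpa_fraction, 0.52, tolerance = 0.02 / 0.52)
  expect_lt(r1$cohort$tawss_voxel_pa, r1$cohort$tawss_fine_pa)
})

test_that("autoplot methods return ggplot objects", {
  f <- linear_fit(printed_cohort(), tawss_whole_pa, mean_pap_mmhg)
  expect_s3_class(ggplot2::autoplot(f), "ggplot")
  expect_s3_class(ggplot2::autoplot(half_sine_waveform(95, 0.95)), "ggplot")
  expect_s3_class(ggplot2::autoplot(cohort_correlation_report(printed_cohort())),
                  "ggplot")
})
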