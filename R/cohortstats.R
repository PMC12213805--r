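#' Ordinary least-squares fit of a cohort relation
#'
#' Fits `response ~ predictor` by OLS (via [stats::lm()]) and reports the
#' coefficient of determination as the squared Pearson correlation.  Used
#' for the cohort-level TAWSS-pressure, stroke-volume-pressure and
#' diameter-pressure relations.
#'
#' @param data a data frame (e.g. [printed_cohort()]).
#' @param predictor,response column names (strings or bare names).
#' @return a `cohort_fit`: list with the underlying `lm`, `slope`,
#'   `intercept`, `r_squared`, `n` and the variable names.
#' @examples
#' linear_fit(printed_cohort(), tawss_whole_pa, mean_pap_mmhg)
#' @export
linear_fit <- function(data, predictor, response) {
  pred <- rlang::as_name(rlang::ensym(predictor))
  resp <- rlang::as_name(rlang::ensym(response))
  x <- data[[pred]]
  y <- data[[resp]]
  if (is.null(x) || is.null(y)) stop_pahemo("Predictor or response column is missing.")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop_pahemo("At least 3 complete observations are required.")
  if (diff(range(x)) == 0) stop_pahemo("Predictor is constant; cannot fit a line.")
  fit <- lm(y ~ x, data = data.frame(x = x, y = y))
  structure(
    list(
      fit = fit,
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      r_squared = summary(fit)$r.squared, n = length(x),
      predictor = pred, response = resp,
      data = tibble(x = x, y = y)
    ),
    class = "cohort_fit"
  )
}

#' @export
print.cohort_fit <- function(x, ...) {
  cat(sprintf(
    "<cohort_fit> %s = %.3f + %.3f * %s  (R^2 = %.3f, n = %d)\n",
    x$response, x$intercept, x$slope, x$predictor, x$r_squared, x$n
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cohort fit
#'
#' @param x a `cohort_fit`.
#' @param ... unused.
#' @return one row per model term, broom-style.
#' @export
tidy.cohort_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = c("(Intercept)", x$predictor),
    estimate = unname(s[, 1]), std.error = unname(s[, 2]),
    statistic = unname(s[, 3]), p.value = unname(s[, 4])
  )
}

#' Glance at a cohort fit
#'
#' @param x a `cohort_fit`.
#' @param ... unused.
#' @return a one-row tibble with `r.squared`, `slope`, `intercept`, `nobs`.
#' @export
glance.cohort_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, slope = x$slope, intercept = x$intercept,
         nobs = x$n)
}

#' CFD-versus-4D-flow validation metrics
#'
#' Per-patient agreement between simulated and measured hemodynamics: the
#' percentage difference of the mean peak-systolic MPA velocity (relative to
#' the 4D-flow measurement) and the absolute difference of the RPA flow
#' fraction.
#'
#' @param cohort a cohort table with paired columns
#'   `mpa_velocity_4dflow_ms` / `mpa_velocity_cfd_ms` and
#'   `rpa_fraction_4dflow` / `rpa_fraction_cfd` (default: the printed
#'   cohort).
#' @return a `validation_report` tibble with per-patient differences;
#'   `glance()` gives the mean and range.
#' @export
validation_metrics <- function(cohort = printed_cohort()) {
  need <- c("mpa_velocity_4dflow_ms", "mpa_velocity_cfd_ms",
            "rpa_fraction_4dflow", "rpa_fraction_cfd")
  if (!all(need %in% names(cohort))) {
    stop_pahemo("Cohort lacks the paired CFD/4D-flow columns.")
  }
  out <- tibble(
    patient = cohort$patient,
    velocity_diff_pct = 100 * abs(cohort$mpa_velocity_cfd_ms -
                                    cohort$mpa_velocity_4dflow_ms) /
      cohort$mpa_velocity_4dflow_ms,
    rpa_fraction_diff = abs(cohort$rpa_fraction_cfd -
                              cohort$rpa_fraction_4dflow)
  )
  class(out) <- c("validation_report", class(out))
  out
}

#' @rdname validation_metrics
#' @param x a `validation_report`.
#' @param ... unused.
#' @export
glance.validation_report <- function(x, ...) {
  tibble(
    mean_velocity_diff_pct = mean(x$velocity_diff_pct),
    min_velocity_diff_pct = min(x$velocity_diff_pct),
    max_velocity_diff_pct = max(x$velocity_diff_pct),
    max_rpa_fraction_diff = max(x$rpa_fraction_diff)
  )
}

#' Cohort correlation report
#'
#' Regresses mean pulmonary arterial pressure on each requested predictor
#' and collects slope, intercept and R^2, plus the scatter data needed for
#' a TAWSS-pressure figure.  Missing predictor columns are listed as
#' skipped rather than failing the whole report.
#'
#' @param cohort a cohort table (default [printed_cohort()]).
#' @param predictors character vector of predictor column names.
#' @param response response column (default `mean_pap_mmhg`).
#' @return a `cohort_correlations` tibble: one row per fitted predictor with
#'   `slope`, `intercept`, `r_squared`, `n` and a `data` list-column;
#'   skipped predictors in `attr(, "skipped")`.
#' @export
cohort_correlation_report <- function(cohort = printed_cohort(),
                                      predictors = c("tawss_whole_pa",
                                                     "tawss_mpa_pa",
                                                     "stroke_volume_ml"),
                                      response = "mean_pap_mmhg") {
  present <- predictors[predictors %in% names(cohort)]
  skipped <- setdiff(predictors, present)
  if (length(skipped)) {
    rlang::inform(paste("Skipping absent predictors:",
                        paste(skipped, collapse = ", ")))
  }
  if (!length(present)) stop_pahemo("No requested predictor is present.")
  out <- purrr::map_dfr(present, function(p) {
    f <- linear_fit(cohort, !!rlang::sym(p), !!rlang::sym(response))
    tibble(predictor = p, response = response, slope = f$slope,
           intercept = f$intercept, r_squared = f$r_squared, n = f$n,
           data = list(f$data))
  })
  class(out) <- c("cohort_correlations", class(out))
  attr(out, "skipped") <- skipped
  out
}

#' Pipeline configuration
#'
#' @param mode `"fixture"` (printed-cohort analyses only) or `"phantom"`
#'   (synthetic studies through the full chain).
#' @param out_dir output directory (created if needed).
#' @param specs named list of [phantom_spec()]s (phantom mode).
#' @param target_mpap_mmhg named numeric vector of per-patient mean PAP
#'   targets for Windkessel tuning (phantom mode); defaults to the printed
#'   cohort values when names match.
#' @param solver_patients names of phantom patients to run through the
#'   pulsatile tube solver (can be empty: the voxel-WSS path needs no
#'   solver).
#' @param solver solver configuration for those runs.
#' @param spacing study voxel spacing (mm).
#' @param seed integer seed.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("fixture", "phantom"),
                            out_dir = tempfile("pahemo-"),
                            specs = list(),
                            target_mpap_mmhg = NULL,
                            solver_patients = character(),
                            solver = solver_config(),
                            spacing = c(2, 2.5, 2.5),
                            seed = 1L) {
  mode <- match.arg(mode)
  structure(
    list(mode = mode, out_dir = out_dir, specs = specs,
         target_mpap_mmhg = target_mpap_mmhg,
         solver_patients = solver_patients, solver = solver,
         spacing = spacing, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Orchestrates the workflow end to end.  In fixture mode it reproduces the
#' printed-cohort analyses (validation metrics and the TAWSS-pressure
#' correlations).  In phantom mode it generates a synthetic 4D-flow study
#' per patient, reconstructs and labels the vessel, quantifies the inlet
#' waveform, stroke volume and branch split, tunes per-branch Windkessel
#' models against the target pressure, estimates voxel-grade TAWSS and its
#' analytic fine-grid reference, and (optionally) runs the pulsatile tube
#' solver with Quemada rheology and the tuned outlet for selected patients.
#' Results are written under `config$out_dir` (cohort CSV, regression JSON
#' and a plain-text log with per-stage timings).
#'
#' @param config a [pipeline_config()].
#' @return a list with the assembled `cohort` tibble, the
#'   `correlations` report, `validation` metrics (fixture mode), per-patient
#'   stage results, and the output paths.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  logf <- function(fmt, ...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                sprintf(fmt, ...)),
        file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      logf("stage %s FAILED: %s", name, conditionMessage(e))
      stop_pahemo(sprintf("Pipeline stage '%s' failed: %s", name,
                          conditionMessage(e)))
    })
    logf("stage %s done in %.2f s", name, proc.time()[["elapsed"]] - t0)
    res
  }

  if (config$mode == "fixture") {
    cohort <- stage("load-cohort", printed_cohort())
    validation <- stage("validation", validation_metrics(cohort))
    correlations <- stage("correlate", cohort_correlation_report(cohort))
    write.csv(cohort, file.path(config$out_dir, "cohort.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      dplyr::select(as_tibble(correlations), -"data"),
      file.path(config$out_dir, "regressions.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA
    )
    return(invisible(list(cohort = cohort, validation = validation,
                          correlations = correlations,
                          out_dir = config$out_dir)))
  }

  specs <- config$specs
  if (!length(specs)) stop_pahemo("Phantom mode needs at least one phantom spec.")
  if (is.null(names(specs))) names(specs) <- sprintf("S%d", seq_along(specs))
  targets <- config$target_mpap_mmhg
  if (is.null(targets)) {
    pc <- printed_cohort()
    targets <- setNames(pc$mean_pap_mmhg, pc$patient)
  }
  per_patient <- list()
  rows <- list()
  for (nm in names(specs)) {
    spec <- specs[[nm]]
    geo <- stage(paste0(nm, ":geometry"),
                 generate_bifurcation_geometry(spec, config$spacing))
    study <- stage(paste0(nm, ":study"),
                   generate_flow_study(spec, geo, spacing = config$spacing))
    seg <- stage(paste0(nm, ":label"),
                 label_regions(geo$mask, geo$spacing, geo$origin))
    inlet <- stage(paste0(nm, ":inlet"), extract_inlet_profile(study, geo))
    wf <- stage(paste0(nm, ":waveform"), flow_waveform(inlet))
    sv <- stroke_volume(wf)
    split <- stage(paste0(nm, ":split"), branch_split(study, geo))
    target <- if (nm %in% names(targets)) targets[[nm]] else 35
    qbar <- mean(wf$flow)
    wk <- list(
      rpa = tune_3ewk(mmhg_to_pa(target), qbar * split$fraction_rpa),
      lpa = tune_3ewk(mmhg_to_pa(target), qbar * split$fraction_lpa)
    )
    coarse <- stage(paste0(nm, ":voxel-wss"), voxel_wss_estimate(study, geo))
    fine <- stage(paste0(nm, ":fine-wss"), phantom_wall_tawss(spec))
    bias <- resolution_bias(mean(fine$tawss_pa), regional_average(coarse))
    solver_run <- NULL
    if (nm %in% config$solver_patients) {
      solver_run <- stage(paste0(nm, ":solver"), {
        run <- simulate_pulsatile_tube(
          radius = spec$mpa_radius, length = 4 * spec$mpa_radius,
          inlet = wf, rheology = rheology_params(),
          outlet = windkessel_params(
            r1 = 1 / (1 / wk$rpa$r1 + 1 / wk$lpa$r1),
            r2 = 1 / (1 / wk$rpa$r2 + 1 / wk$lpa$r2),
            c = wk$rpa$c + wk$lpa$c
          ),
          config = config$solver
        )
        converged_final_cycle(run)
      })
    }
    tw_solver <- if (!is.null(solver_run)) {
      regional_average(tawss(wall_shear_stress(solver_run)), "mpa")
    } else NA_real_
    rows[[nm]] <- tibble(
      patient = nm, period_s = spec$period,
      stroke_volume_ml = sv,
      rpa_fraction = split$fraction_rpa,
      mean_pap_mmhg = target,
      tawss_voxel_pa = regional_average(coarse),
      tawss_fine_pa = mean(fine$tawss_pa),
      tawss_solver_mpa_pa = tw_solver
    )
    per_patient[[nm]] <- list(geometry = geo, segmentation = seg,
                              waveform = wf, split = split, windkessel = wk,
                              voxel_tawss = coarse, fine_tawss = fine,
                              bias = bias, solver = solver_run)
  }
  cohort <- dplyr::bind_rows(rows)
  correlations <- if (nrow(cohort) >= 3L) {
    stage("correlate", cohort_correlation_report(
      cohort, predictors = c("tawss_fine_pa", "tawss_voxel_pa",
                             "stroke_volume_ml")
    ))
  } else {
    logf("stage correlate skipped: fewer than 3 patients")
    NULL
  }
  write.csv(cohort, file.path(config$out_dir, "cohort.csv"), row.names = FALSE)
  if (!is.null(correlations)) {
    jsonlite::write_json(
      dplyr::select(as_tibble(correlations), -"data"),
      file.path(config$out_dir, "regressions.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA
    )
  }
  invisible(list(cohort = cohort, correlations = correlations,
                 patients = per_patient, out_dir = config$out_dir))
}
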