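#' Printed PAH study cohort
#'
#' Per-patient records for the seven-patient PAH pilot cohort shipped with
#' the package: cardiac cycle length, stroke volume, measured RPA flow
#' fraction, invasively measured (right heart catheter) mean pulmonary
#' arterial pressure, tuned three-element Windkessel parameters for both
#' branches (SI units: resistances in Pa s m^-3, compliances in m^3 Pa^-1),
#' the paired 4D-flow/CFD validation measurements (branch flow fractions and
#' mean peak-systolic MPA velocity) and the regional spatially averaged TAWSS
#' values.
#'
#' @return a tibble with 7 rows (patients P1-P7).
#' @examples
#' printed_cohort()$stroke_volume_ml
#' @export
printed_cohort <- function() {
  path <- system.file("extdata", "printed_cohort.csv", package = "pahemo",
                      mustWork = TRUE)
  ch <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  stopifnot(nrow(ch) == 7L)
  frac_sum <- ch$rpa_fraction_4dflow + ch$lpa_fraction_4dflow
  if (any(abs(frac_sum - 1) > 0.01)) {
    stop_pahemo("Corrupt cohort fixture: branch fractions do not sum to 1.")
  }
  ch
}

#' Printed plane-based TAWSS comparison
#'
#' Cohort-averaged (and min/max) TAWSS on analysis planes in the MPA, RPA
#' and LPA, evaluated both from high-resolution CFD and directly from
#' voxel-resolution 4D-flow MRI.  The 4D-flow values are substantially lower
#' than the CFD values, the resolution gap that [voxel_wss_estimate()] and
#' [resolution_bias()] reproduce mechanistically on phantoms.
#'
#' @return a tibble with one row per region.
#' @export
printed_plane_tawss <- function() {
  path <- system.file("extdata", "printed_plane_tawss.csv", package = "pahemo",
                      mustWork = TRUE)
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Generate a synthetic cohort with a known TAWSS-pressure relation
#'
#' Draws `n` synthetic patients whose whole-geometry TAWSS is uniform on
#' `tawss_range` and whose mean pulmonary arterial pressure follows the
#' linear rule `mPAP = intercept + slope * TAWSS + N(0, noise_sd)`.  Used
#' for parameter-recovery checks of the cohort regression stage.  Defaults
#' echo the scale of the printed cohort (an inverse TAWSS-pressure
#' relation).
#'
#' @param n number of synthetic patients.
#' @param slope linear slope (mmHg per Pa), negative by default.
#' @param intercept intercept (mmHg).
#' @param noise_sd Gaussian noise on mPAP (mmHg).
#' @param tawss_range range of TAWSS values (Pa).
#' @param seed integer seed.
#' @return a tibble with columns `patient`, `tawss_whole_pa`,
#'   `mean_pap_mmhg`.
#' @export
generate_synthetic_cohort <- function(n = 200L, slope = -11.6,
                                      intercept = 68.2, noise_sd = 5,
                                      tawss_range = c(0.6, 3.7), seed = 1L) {
  if (n < 3L) stop_pahemo("A cohort needs at least 3 patients.")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  tawss <- runif(n, tawss_range[1], tawss_range[2])
  mpap <- intercept + slope * tawss + rnorm(n, sd = noise_sd)
  tibble(
    patient = sprintf("S%03d", seq_len(n)),
    tawss_whole_pa = tawss,
    mean_pap_mmhg = mpap
  )
}
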