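#' Peak pulmonary arterial pressure from echocardiography
#'
#' Simplified Bernoulli estimate of peak (systolic) pulmonary arterial
#' pressure from the peak tricuspid regurgitant jet velocity:
#' `peak PAP [mmHg] = 4 v^2 + RAP`, with `v` in m/s and the right atrial
#' pressure `RAP` in mmHg (clinician-estimated from inferior vena cava
#' appearance).
#'
#' @param tricuspid_velocity peak tricuspid valve velocity (m/s), >= 0.
#' @param rap right atrial pressure (mmHg), >= 0.
#' @return peak PAP (mmHg).
#' @examples
#' peak_pap_bernoulli(3.0, 8)   # 44 mmHg
#' @export
peak_pap_bernoulli <- function(tricuspid_velocity, rap) {
  if (any(!is.finite(tricuspid_velocity)) || any(!is.finite(rap)) ||
      any(tricuspid_velocity < 0) || any(rap < 0)) {
    stop_pahemo("Tricuspid velocity and RAP must be finite and non-negative.")
  }
  4 * tricuspid_velocity^2 + rap
}

#' Mean pulmonary arterial pressure from peak pressure
#'
#' Chemla's empirical relation `mean PAP = 0.61 * peak PAP + 2` (mmHg).
#'
#' @param peak_pap peak systolic PAP (mmHg), >= 0.
#' @return mean PAP (mmHg).
#' @examples
#' mean_pap_from_peak(44)   # 28.84 mmHg
#' @export
mean_pap_from_peak <- function(peak_pap) {
  if (any(peak_pap < 0)) stop_pahemo("Peak PAP must be non-negative.")
  0.61 * peak_pap + 2
}

#' Classify pulmonary hypertension
#'
#' Pulmonary hypertension is defined by a mean pulmonary arterial pressure
#' strictly above 20 mmHg.
#'
#' @param mean_pap mean PAP (mmHg).
#' @return logical: `TRUE` if `mean_pap > 20`.
#' @export
classify_ph <- function(mean_pap) {
  mean_pap > 20
}

#' Full echo-based pressure estimate
#'
#' Convenience wrapper chaining the simplified Bernoulli and Chemla
#' relations, returning a one-row tibble per measurement.
#'
#' @inheritParams peak_pap_bernoulli
#' @return a tibble with columns `peak_pap_mmhg`, `mean_pap_mmhg`,
#'   `mean_pap_pa`, `ph` (classification) and `source = "echo"`.
#' @export
estimate_pressure_echo <- function(tricuspid_velocity, rap) {
  peak <- peak_pap_bernoulli(tricuspid_velocity, rap)
  m <- mean_pap_from_peak(peak)
  tibble(
    peak_pap_mmhg = peak,
    mean_pap_mmhg = m,
    mean_pap_pa = mmhg_to_pa(m),
    ph = classify_ph(m),
    source = "echo"
  )
}
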