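#' Three-element Windkessel parameters
#'
#' Proximal resistance `R1` in series with a parallel distal resistance `R2`
#' and compliance `C`, representing the vascular bed downstream of one
#' pulmonary branch.  Units follow the clinical convention: resistances in
#' Pa s m^-3, compliance in m^3 Pa^-1.
#'
#' @param r1 proximal resistance (Pa s m^-3), >= 0.
#' @param r2 distal resistance (Pa s m^-3), > 0.
#' @param c compliance (m^3 Pa^-1), > 0.
#' @param distal_pressure reference (venous) pressure (Pa), default 0.
#' @return a list of class `windkessel_params`; `tau` is the RC time
#'   constant `R2 * C` (s).
#' @export
windkessel_params <- function(r1, r2, c, distal_pressure = 0) {
  if (r1 < 0 || r2 <= 0 || c <= 0) {
    stop_pahemo("Windkessel parameters require R1 >= 0, R2 > 0, C > 0.")
  }
  structure(
    list(r1 = r1, r2 = r2, c = c, distal_pressure = distal_pressure,
         tau = r2 * c),
    class = "windkessel_params"
  )
}

#' @export
print.windkessel_params <- function(x, ...) {
  cat(sprintf(
    "<windkessel_params> R1 = %.3g, R2 = %.3g Pa s m^-3, C = %.3g m^3 Pa^-1 (tau = %.3f s)\n",
    x$r1, x$r2, x$c, x$tau
  ))
  invisible(x)
}

#' Tune a three-element Windkessel to non-invasive estimates
#'
#' The total branch resistance is fixed by the target mean pressure and the
#' cycle-mean branch flow, `R_total = (P_target - P_distal) / Q_mean`; it is
#' split into a proximal fraction `f` (`R1 = f * R_total`) and a distal
#' remainder (`R2 = (1 - f) * R_total`), and the compliance follows from a
#' prescribed RC time constant, `C = tau / R2`.  Back-derivation from
#' published PAH parameter sets shows `f` in roughly 0.04-0.21 and `tau` in
#' 0.60-0.72 s, so the defaults sit mid-range.
#'
#' @param mean_pap_target target cycle-mean pressure (Pa).
#' @param branch_mean_flow cycle-mean branch flow (m^3/s), > 0.
#' @param proximal_fraction fraction `f` of the total resistance placed
#'   proximally, in `[0, 1)` (default 0.1).
#' @param time_constant Windkessel time constant `tau = R2 * C` (s), > 0
#'   (default 0.7).
#' @param distal_pressure reference pressure (Pa), default 0.
#' @return a [windkessel_params()].
#' @examples
#' tune_3ewk(mmhg_to_pa(38.4), 6.2e-5)
#' @export
tune_3ewk <- function(mean_pap_target, branch_mean_flow,
                      proximal_fraction = 0.1, time_constant = 0.7,
                      distal_pressure = 0) {
  if (branch_mean_flow <= 0) {
    stop_pahemo("Branch mean flow must be positive to tune a Windkessel.")
  }
  if (proximal_fraction < 0 || proximal_fraction >= 1) {
    stop_pahemo("`proximal_fraction` must lie in [0, 1).")
  }
  if (time_constant <= 0) stop_pahemo("`time_constant` must be positive.")
  r_total <- (mean_pap_target - distal_pressure) / branch_mean_flow
  if (r_total <= 0) {
    stop_pahemo("Target pressure must exceed the distal pressure.")
  }
  r1 <- proximal_fraction * r_total
  r2 <- (1 - proximal_fraction) * r_total
  windkessel_params(r1, r2, time_constant / r2, distal_pressure)
}

#' Integrate a three-element Windkessel model
#'
#' Solves `C dPc/dt = Q(t) - (Pc - P_distal)/R2` with classic fourth-order
#' Runge-Kutta at fixed step `dt`, the prescribed flow interpolated
#' periodically, and returns the proximal pressure `P(t) = R1 Q(t) + Pc(t)`
#' over all cycles.
#'
#' @param params a [windkessel_params()].
#' @param waveform a [flow_waveform()] (one cycle, repeated periodically).
#' @param n_cycles number of cardiac cycles to integrate (>= 3).
#' @param dt time step (s), at most `T/50` (default 0.005).
#' @param pc0 initial capacitor pressure (Pa), default 0.
#' @return a `pressure_waveform`: tibble with `time` (s), `pressure` (Pa),
#'   `flow` (m^3/s) and `cycle` (1-based index), plus a `period` attribute.
#' @export
simulate_3ewk <- function(params, waveform, n_cycles = 6L, dt = 0.005,
                          pc0 = 0) {
  period <- wf_period(waveform)
  if (n_cycles < 3L) stop_pahemo("At least three cycles are required.")
  if (dt > period / 50) stop_pahemo("`dt` must be at most T/50.")
  n_per <- round(period / dt)
  dt <- period / n_per  # snap so cycles align with the step grid
  n <- n_per * n_cycles
  t <- seq(0, by = dt, length.out = n + 1L)
  q <- waveform_interp(waveform, t)
  qh <- waveform_interp(waveform, t + dt / 2)
  pc <- numeric(n + 1L)
  pc[1] <- pc0
  dpc <- function(p, qq) (qq - (p - params$distal_pressure) / params$r2) / params$c
  for (i in seq_len(n)) {
    k1 <- dpc(pc[i], q[i])
    k2 <- dpc(pc[i] + dt / 2 * k1, qh[i])
    k3 <- dpc(pc[i] + dt / 2 * k2, qh[i])
    k4 <- dpc(pc[i] + dt * k3, q[i + 1L])
    pc[i + 1L] <- pc[i] + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  p <- params$r1 * q + pc
  if (any(!is.finite(p))) {
    stop_pahemo("Windkessel integration produced non-finite pressures.")
  }
  out <- tibble(
    time = t, pressure = p, flow = q,
    cycle = pmin(floor(t / period) + 1L, n_cycles)
  )
  attr(out, "period") <- period
  attr(out, "params") <- params
  class(out) <- c("pressure_waveform", class(out))
  out
}

#' Cycle-to-cycle periodicity metric
#'
#' Percentage variation between two cycles of a waveform:
#' `100 * max|a - b| / max|b|`.  A simulation is considered periodic when
#' the metric between the final two cycles falls below 1%.
#'
#' @param cycle_a,cycle_b numeric vectors of equal length (one cycle each),
#'   or a `pressure_waveform` from which the last two cycles are taken when
#'   only `cycle_a` is given.
#' @return variation in percent.
#' @export
periodicity_metric <- function(cycle_a, cycle_b = NULL) {
  if (inherits(cycle_a, "pressure_waveform") && is.null(cycle_b)) {
    nc <- max(cycle_a$cycle)
    b <- cycle_a$pressure[cycle_a$cycle == nc]
    a <- cycle_a$pressure[cycle_a$cycle == nc - 1L]
    n <- min(length(a), length(b))
    cycle_a <- a[seq_len(n)]; cycle_b <- b[seq_len(n)]
  }
  if (length(cycle_a) != length(cycle_b)) {
    stop_pahemo("Cycles must have equal length.")
  }
  ref <- max(abs(cycle_b))
  if (ref == 0) stop_pahemo("Reference cycle is identically zero.")
  100 * max(abs(cycle_a - cycle_b)) / ref
}

#' Cycle-averaged pressure
#'
#' Trapezoidal average of a pressure waveform over one complete cycle,
#' reported in both Pa and mmHg.
#'
#' @param waveform a `pressure_waveform` from [simulate_3ewk()].
#' @param cycle which cycle to average (default: the last complete one).
#' @return a tibble with `pressure_pa` and `pressure_mmhg`.
#' @export
mean_pressure <- function(waveform, cycle = max(waveform$cycle)) {
  idx <- which(waveform$cycle == cycle)
  if (!length(idx)) stop_pahemo("Requested cycle is not present.")
  if (max(idx) < nrow(waveform)) idx <- c(idx, max(idx) + 1L)
  t <- waveform$time[idx]
  p <- waveform$pressure[idx]
  period <- attr(waveform, "period")
  if (max(t) - min(t) < period - period / 25) {
    stop_pahemo("Requested cycle is incomplete.")
  }
  pbar <- sum(diff(t) * (head(p, -1) + tail(p, -1)) / 2) / (max(t) - min(t))
  tibble(pressure_pa = pbar, pressure_mmhg = pa_to_mmhg(pbar))
}
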