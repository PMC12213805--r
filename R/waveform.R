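#' Time-resolved volumetric flow waveform
#'
#' A `flow_waveform` holds one cardiac cycle of volumetric flow rate: sample
#' times in `[0, period)` (seconds) and flow rate in m^3/s.  Stroke volume is
#' the integral of the waveform over the cycle (see [stroke_volume()]).
#'
#' `flow_waveform()` is a generic: called with a numeric time vector it acts
#' as the constructor; called with an `inlet_profile` (see
#' [extract_inlet_profile()]) it integrates the through-plane velocity over
#' the lumen at every frame, `Q(t_f) = sum(v * dA)`.
#'
#' @param time numeric vector of sample times (s), strictly increasing, all in
#'   `[0, period)`; or an `inlet_profile`.
#' @param flow numeric vector of volumetric flow rates (m^3/s), same length as
#'   `time` (at least 10 samples).
#' @param period cardiac cycle length (s).
#' @param ... passed between methods.
#' @return a tibble of class `flow_waveform` with columns `time`, `flow` and a
#'   `period` attribute.
#' @seealso [half_sine_waveform()], [flow_harmonics()], [stroke_volume()]
#' @export
flow_waveform <- function(time, ...) UseMethod("flow_waveform")

#' @rdname flow_waveform
#' @export
flow_waveform.inlet_profile <- function(time, ...) {
  profile <- time
  q <- as.numeric(colSums(profile$velocity) * profile$area_mm2 * 1e-6)
  flow_waveform(profile$frame_times, q, profile$period)
}

#' @rdname flow_waveform
#' @export
flow_waveform.numeric <- function(time, flow, period, ...) {
  if (length(time) != length(flow)) {
    stop_pahemo("`time` and `flow` must have the same length.")
  }
  if (length(time) < 10) {
    stop_pahemo("A flow waveform needs at least 10 samples per cycle.")
  }
  if (any(diff(time) <= 0) || any(time < 0) || any(time >= period)) {
    stop_pahemo("`time` must be strictly increasing and lie in [0, period).")
  }
  out <- tibble(time = as.numeric(time), flow = as.numeric(flow))
  attr(out, "period") <- as.numeric(period)
  class(out) <- c("flow_waveform", class(out))
  out
}

#' @export
print.flow_waveform <- function(x, ...) {
  cat(sprintf(
    "<flow_waveform> %d samples, period %.3f s, stroke volume %.1f mL\n",
    nrow(x), wf_period(x), stroke_volume(x)
  ))
  invisible(x)
}

wf_period <- function(waveform) attr(waveform, "period")

#' Half-sine systolic ejection waveform
#'
#' Default cardiac waveform of the phantom generator: a half-sine ejection
#' lobe over the systolic fraction of the cycle followed by zero diastolic
#' flow, scaled so the cycle integral equals the requested stroke volume.
#' The peak flow is `3*pi*SV / (2*T)` for the default one-third systole.
#'
#' @param stroke_volume_ml stroke volume (mL), positive.
#' @param period cardiac cycle length (s).
#' @param systole_fraction fraction of the cycle occupied by ejection
#'   (default 1/3).
#' @param n_samples samples per cycle (default 256).
#' @return a [flow_waveform()].
#' @export
half_sine_waveform <- function(stroke_volume_ml, period,
                               systole_fraction = 1 / 3, n_samples = 256L) {
  if (stroke_volume_ml <= 0) stop_pahemo("Stroke volume must be positive.")
  if (systole_fraction <= 0 || systole_fraction >= 1) {
    stop_pahemo("`systole_fraction` must be in (0, 1).")
  }
  ts <- period * systole_fraction
  amp <- pi * stroke_volume_ml * 1e-6 / (2 * ts)
  t <- seq(0, period, length.out = n_samples + 1L)[seq_len(n_samples)]
  q <- ifelse(t < ts, amp * sin(pi * t / ts), 0)
  flow_waveform(t, q, period)
}

#' Evaluate a waveform by periodic linear interpolation
#'
#' @param waveform a [flow_waveform()].
#' @param t times (s); interpreted modulo the period.
#' @return flow rates (m^3/s) at `t`.
#' @export
waveform_interp <- function(waveform, t) {
  period <- wf_period(waveform)
  tt <- waveform$time
  qq <- waveform$flow
  # wrap the first sample to the end so interpolation is periodic
  tt <- c(tt, tt[1] + period)
  qq <- c(qq, qq[1])
  approx(tt, qq, xout = (t %% period) + ifelse((t %% period) < tt[1], period, 0),
         rule = 2)$y
}

#' Fourier flow harmonics of a waveform
#'
#' Decomposes one cycle of a flow waveform into complex Fourier coefficients
#' `c_k` such that `Q(t) = Re( sum_k c_k exp(i k w t) )` with `w = 2*pi/T`.
#' `c_0` is real and equals the cycle-mean flow, so truncating the series
#' never changes the stroke volume.  Requires uniformly spaced samples.
#'
#' @param waveform a [flow_waveform()] with uniform sampling.
#' @param n_harmonics number of nonzero-frequency harmonics retained.
#' @return complex vector `c(c_0, c_1, ..., c_K)` with attributes `period`.
#' @export
flow_harmonics <- function(waveform, n_harmonics = 10L) {
  n <- nrow(waveform)
  dt <- diff(waveform$time)
  if (diff(range(dt)) > 1e-9 * mean(dt)) {
    stop_pahemo("`flow_harmonics()` requires uniformly sampled waveforms.")
  }
  n_harmonics <- min(as.integer(n_harmonics), n %/% 2L - 1L)
  co <- fft(waveform$flow) / n
  h <- c(Re(co[1]) + 0i, 2 * co[seq_len(n_harmonics) + 1L])
  # account for samples starting at time[1] (possibly nonzero)
  w <- 2 * pi / wf_period(waveform)
  h <- h * exp(-1i * w * seq(0L, n_harmonics) * waveform$time[1])
  attr(h, "period") <- wf_period(waveform)
  h
}

#' Evaluate a harmonic flow series
#'
#' @param harmonics complex coefficients from [flow_harmonics()] (or supplied
#'   directly, with a `period` attribute or `period` given).
#' @param t times (s).
#' @param period cycle length (s); defaults to the `period` attribute.
#' @return flow rates (m^3/s).
#' @export
harmonics_flow <- function(harmonics, t, period = attr(harmonics, "period")) {
  if (is.null(period)) stop_pahemo("Harmonics need a `period`.")
  w <- 2 * pi / period
  k <- seq_along(harmonics) - 1L
  ph <- exp(1i * outer(k, t) * w)          # (K+1) x length(t)
  as.numeric(Re(t(ph) %*% as.complex(harmonics)))
}
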