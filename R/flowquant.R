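# Shared plane sampler: through-plane and in-plane velocities of a flow
# study on a regular in-plane grid, lumen-masked against a vessel geometry.
plane_velocity_samples <- function(study, geometry, plane,
                                   grid_spacing = min(study$spacing) / 2,
                                   region = NULL) {
  extent <- sum(dim(geometry$mask) * geometry$spacing) / 2
  pg <- plane_grid(plane, extent, grid_spacing)
  idx <- world_to_index(pg$points, study$origin, study$spacing)
  maskn <- array(as.numeric(geometry$mask), dim(geometry$mask))
  lumen <- trilinear(maskn, idx) >= 0.5
  if (!is.null(region)) {
    regn <- array(as.numeric(geometry$labels %in% region), dim(geometry$labels))
    in_region <- trilinear(regn, idx) >= 0.5
    lumen <- lumen & in_region
    if (!any(lumen)) {
      stop_pahemo("Plane does not intersect the requested vessel region.")
    }
  }
  if (!any(lumen)) stop_pahemo("Plane does not intersect the vessel lumen.")
  keep <- which(lumen)
  nf <- length(study$frame_times)
  vmat <- array(0, dim = c(length(keep), 3L, nf))
  comp <- list(study$velocity$vx, study$velocity$vy, study$velocity$vz)
  kidx <- idx[keep, , drop = FALSE]
  for (f in seq_len(nf)) {
    for (c3 in 1:3) {
      vmat[, c3, f] <- trilinear(comp[[c3]][, , , f], kidx)
    }
  }
  list(points = pg$points[keep, , drop = FALSE], idx = kidx,
       area_mm2 = pg$area_mm2, velocity = vmat, plane = plane,
       n_total = nrow(pg$points))
}

#' Extract the inlet velocity profile from a 4D-flow study
#'
#' Interpolates (trilinearly) the through-plane velocity component on a
#' regular in-plane grid across the inlet plane, masked to the vessel lumen.
#' Samples outside the lumen carry zero velocity; the same sample set is
#' used at every frame.
#'
#' @param study a `flow_study` (see [generate_flow_study()]).
#' @param geometry a `vessel_geometry` sharing the study grid.
#' @param plane an [analysis_plane()]; defaults to the geometry's inlet
#'   plane.  Must intersect the MPA region.
#' @param grid_spacing in-plane sample spacing (mm), at most the voxel
#'   spacing (default: half the smallest voxel spacing).
#' @return an `inlet_profile`: list with `points` (n x 3, mm), `area_mm2`
#'   (sample area element), `velocity` (n x F matrix of through-plane
#'   velocity, m/s), `frame_times`, `period`, `plane`.
#' @export
extract_inlet_profile <- function(study, geometry,
                                  plane = geometry$inlet_plane,
                                  grid_spacing = min(study$spacing) / 2) {
  if (grid_spacing > min(study$spacing) + 1e-9) {
    stop_pahemo("`grid_spacing` must not exceed the voxel spacing.")
  }
  s <- plane_velocity_samples(study, geometry, plane, grid_spacing,
                              region = 1L)
  nf <- length(study$frame_times)
  vthrough <- vapply(seq_len(nf), function(f) {
    s$velocity[, , f] %*% plane$normal
  }, numeric(nrow(s$points)))
  structure(
    list(points = s$points, area_mm2 = s$area_mm2,
         velocity = matrix(vthrough, nrow = nrow(s$points)),
         frame_times = study$frame_times, period = study$period,
         plane = plane),
    class = "inlet_profile"
  )
}

#' @export
print.inlet_profile <- function(x, ...) {
  cat(sprintf("<inlet_profile> %d lumen samples x %d frames (dA = %.2f mm^2)\n",
              nrow(x$velocity), ncol(x$velocity), x$area_mm2))
  invisible(x)
}

#' Stroke volume of a flow waveform
#'
#' Periodic trapezoidal integral of the volumetric flow rate over one
#' cardiac cycle, in mL.  Regurgitant (negative) flow reduces the stroke
#' volume: the integral is signed.
#'
#' @param waveform a [flow_waveform()] covering exactly one cycle.
#' @return stroke volume (mL).
#' @export
stroke_volume <- function(waveform) {
  cycle_integral(waveform$time, waveform$flow, wf_period(waveform)) * 1e6
}

# trapezoidal integral over one period with periodic wrap-around
cycle_integral <- function(t, y, period) {
  tt <- c(t, t[1] + period)
  yy <- c(y, y[1])
  sum(diff(tt) * (head(yy, -1) + tail(yy, -1)) / 2)
}

#' Branch flow split
#'
#' Fraction of flow reporting to the right and left pulmonary artery,
#' computed from cycle-mean branch flows through the two outlet planes and
#' normalised over their sum (so the two fractions add to 1 exactly, as the
#' measurement is usually reported).
#'
#' @param study a `flow_study`.
#' @param geometry a `vessel_geometry` with `outlet_planes`.
#' @param lpa_plane,rpa_plane [analysis_plane()]s cutting the branches;
#'   default to the geometry's outlet planes.
#' @return a tibble with `fraction_rpa` and `fraction_lpa`.
#' @export
branch_split <- function(study, geometry,
                         lpa_plane = geometry$outlet_planes$lpa,
                         rpa_plane = geometry$outlet_planes$rpa) {
  mean_branch_flow <- function(plane, region) {
    s <- plane_velocity_samples(study, geometry, plane, region = region)
    q <- vapply(seq_along(study$frame_times), function(f) {
      sum(s$velocity[, , f] %*% plane$normal) * s$area_mm2 * 1e-6
    }, numeric(1))
    abs(mean(q))
  }
  q_lpa <- mean_branch_flow(lpa_plane, 2L)
  q_rpa <- mean_branch_flow(rpa_plane, 3L)
  if (q_lpa + q_rpa <= 0) {
    stop_pahemo("Zero total branch flow; cannot compute a flow split.")
  }
  tibble(
    fraction_rpa = q_rpa / (q_lpa + q_rpa),
    fraction_lpa = q_lpa / (q_lpa + q_rpa)
  )
}

#' Mean peak-systolic velocity on a plane
#'
#' Peak systole is defined as the cardiac frame with the maximum inlet
#' volumetric flow.  The statistic is the lumen-average over the plane of
#' the velocity magnitude at that frame (through-plane component available
#' via `mode = "component"`).
#'
#' @param study a `flow_study`.
#' @param geometry a `vessel_geometry`.
#' @param plane plane in the main pulmonary artery (defaults to the inlet
#'   plane).
#' @param mode `"magnitude"` (default) or `"component"`.
#' @return mean peak-systolic velocity (m/s).
#' @export
mean_peak_systolic_velocity <- function(study, geometry,
                                        plane = geometry$inlet_plane,
                                        mode = c("magnitude", "component")) {
  mode <- match.arg(mode)
  inlet <- extract_inlet_profile(study, geometry)
  qf <- colSums(inlet$velocity) * inlet$area_mm2
  fpk <- which.max(abs(qf))
  s <- plane_velocity_samples(study, geometry, plane, region = 1L)
  v <- s$velocity[, , fpk]
  val <- switch(mode,
    magnitude = mean(sqrt(rowSums(v^2))),
    component = mean(abs(v %*% plane$normal))
  )
  as.numeric(val)
}
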