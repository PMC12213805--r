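#' Phantom specification for a synthetic 4D-flow study
#'
#' Describes an idealised pulmonary-artery bifurcation (a main pulmonary
#' artery splitting into left and right branches) together with the pulsatile
#' flow conditions used to build a synthetic 4D-flow MRI study with an
#' analytically known (Womersley) velocity field.  The flow defaults mirror a
#' typical PAH patient: cycle length 0.95 s, stroke volume 95 mL, 62% of
#' inlet flow to the RPA.
#'
#' Geometry defaults use a dilated main pulmonary artery (radius 17.5 mm,
#' i.e. 35 mm diameter) as seen in pulmonary hypertension, with branch radii
#' 10.5 mm (LPA) and 12 mm (RPA).  The LPA leaves the bifurcation towards
#' negative x, the RPA towards positive x.
#'
#' @param mpa_radius main pulmonary artery radius (m).
#' @param branch_radii named vector `c(lpa =, rpa =)` of branch radii (m).
#'   Setting either radius to zero degenerates the phantom to a single
#'   straight tube labelled entirely MPA.
#' @param branch_angles named vector `c(lpa =, rpa =)` of branch angles from
#'   the MPA axis (degrees).
#' @param mpa_length,branch_length segment lengths (m).
#' @param period cardiac cycle length T (s).
#' @param stroke_volume_ml stroke volume per beat (mL).
#' @param rpa_fraction fraction of inlet flow sent to the RPA, in (0, 1).
#' @param systole_fraction fraction of the cycle occupied by the half-sine
#'   ejection lobe (default 1/3).
#' @param waveform optional [flow_waveform()] overriding the default
#'   half-sine shape (it is rescaled to `stroke_volume_ml`).
#' @param n_harmonics flow harmonics used for the analytic field.
#' @param noise_sd additive Gaussian velocity noise (m/s).
#' @param venc velocity-encoding limit (m/s); the generator refuses
#'   specifications whose analytic peak velocity exceeds it.
#' @param nu kinematic viscosity of the analytic field (m^2/s); defaults to
#'   the high-shear Quemada viscosity over a blood density of 1060 kg/m^3.
#' @param seed integer seed for the noise generator.
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(mpa_radius = 0.0175,
                         branch_radii = c(lpa = 0.0105, rpa = 0.0120),
                         branch_angles = c(lpa = 45, rpa = 40),
                         mpa_length = 0.05, branch_length = 0.035,
                         period = 0.95, stroke_volume_ml = 95,
                         rpa_fraction = 0.62,
                         systole_fraction = 1 / 3,
                         waveform = NULL,
                         n_harmonics = 10L,
                         noise_sd = 0, venc = 2.0,
                         nu = unname(viscosity_bounds()["mu_inf"]) / 1060,
                         seed = 1L) {
  if (stroke_volume_ml <= 0) stop_pahemo("Stroke volume must be positive.")
  if (rpa_fraction <= 0 || rpa_fraction >= 1) {
    stop_pahemo("`rpa_fraction` must lie strictly in (0, 1).")
  }
  if (mpa_radius <= 0) stop_pahemo("`mpa_radius` must be positive.")
  if (any(branch_radii < 0)) stop_pahemo("Branch radii must be non-negative.")
  if (is.null(names(branch_radii))) names(branch_radii) <- c("lpa", "rpa")
  if (is.null(names(branch_angles))) names(branch_angles) <- c("lpa", "rpa")
  structure(
    list(mpa_radius = mpa_radius, branch_radii = branch_radii,
         branch_angles = branch_angles, mpa_length = mpa_length,
         branch_length = branch_length, period = period,
         stroke_volume_ml = stroke_volume_ml, rpa_fraction = rpa_fraction,
         systole_fraction = systole_fraction, waveform = waveform,
         n_harmonics = as.integer(n_harmonics), noise_sd = noise_sd,
         venc = venc, nu = nu, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# Limb axes of the phantom: list of (name, origin A, unit direction d,
# length, radius).  Degenerate specs (a zero branch radius) collapse to a
# single MPA tube.
phantom_limbs <- function(spec) {
  degenerate <- any(spec$branch_radii <= 0)
  if (degenerate) {
    return(list(mpa = list(
      name = "mpa", A = c(0, 0, 0), d = c(0, 0, 1),
      len = spec$mpa_length + spec$branch_length, radius = spec$mpa_radius
    )))
  }
  bif <- c(0, 0, spec$mpa_length)
  th <- spec$branch_angles * pi / 180
  list(
    mpa = list(name = "mpa", A = c(0, 0, 0), d = c(0, 0, 1),
               len = spec$mpa_length, radius = spec$mpa_radius),
    lpa = list(name = "lpa", A = bif,
               d = c(-sin(th[["lpa"]]), 0, cos(th[["lpa"]])),
               len = spec$branch_length, radius = spec$branch_radii[["lpa"]]),
    rpa = list(name = "rpa", A = bif,
               d = c(sin(th[["rpa"]]), 0, cos(th[["rpa"]])),
               len = spec$branch_length, radius = spec$branch_radii[["rpa"]])
  )
}

# Axial/radial coordinates of points in a limb frame.  points: n x 3 matrix
# (m).  For the MPA the axial coordinate is not clamped (plain cylinder, flat
# ends); branches are capsules (clamped, rounded start blending the
# junction).
limb_coords <- function(points, limb, clamp = !identical(limb$name, "mpa")) {
  rel <- sweep(points, 2, limb$A)
  s <- as.numeric(rel %*% limb$d)
  sc <- if (clamp) pmin(pmax(s, 0), limb$len) else s
  ax <- outer(sc, limb$d)
  rho <- sqrt(rowSums((rel - ax)^2))
  list(s = s, s_clamped = sc, rho = rho)
}

# limb id per point: 0 outside, 1 mpa, 2 lpa, 3 rpa.  The MPA cylinder wins
# where it overlaps a branch capsule near the junction; between the two
# branches the deeper one (smaller rho - radius) wins.
phantom_label_points <- function(points, limbs) {
  n <- nrow(points)
  lab <- integer(n)
  co <- limb_coords(points, limbs$mpa)
  in_mpa <- co$s >= 0 & co$s <= limbs$mpa$len & co$rho <= limbs$mpa$radius
  lab[in_mpa] <- 1L
  if (length(limbs) == 3L) {
    depth_l <- rep(Inf, n); depth_r <- rep(Inf, n)
    col <- limb_coords(points, limbs$lpa)
    cor <- limb_coords(points, limbs$rpa)
    inl <- col$rho <= limbs$lpa$radius & col$s <= limbs$lpa$len
    inr <- cor$rho <= limbs$rpa$radius & cor$s <= limbs$rpa$len
    depth_l[inl] <- col$rho[inl] - limbs$lpa$radius
    depth_r[inr] <- cor$rho[inr] - limbs$rpa$radius
    branch <- lab == 0L & (inl | inr)
    lab[branch & depth_l <= depth_r] <- 2L
    lab[branch & depth_r < depth_l] <- 3L
  }
  lab
}

#' Generate a voxelised bifurcation geometry
#'
#' Voxelises the phantom's Y-shaped vessel onto a regular grid, labels each
#' lumen voxel as MPA, LPA or RPA, and attaches an inlet analysis plane at
#' the MPA base plus one outlet plane per branch.
#'
#' @param spec a [phantom_spec()].
#' @param spacing voxel spacing in mm, length 3 (default `c(2, 2.5, 2.5)`,
#'   matching clinical 4D-flow resolution).
#' @return a `vessel_geometry`: list with `mask` (logical array), `labels`
#'   (integer array: 0 outside, 1 MPA, 2 LPA, 3 RPA), `spacing` (mm),
#'   `origin` (mm, world position of voxel `[1,1,1]`'s centre),
#'   `inlet_plane`, `outlet_planes`, and phantom metadata in `meta`.
#' @export
generate_bifurcation_geometry <- function(spec, spacing = c(2, 2.5, 2.5)) {
  if (any(spacing <= 0)) stop_pahemo("Voxel spacing must be positive.")
  limbs <- phantom_limbs(spec)
  radii <- vapply(limbs, function(l) l$radius, numeric(1))
  if (any(2 * radii * 1000 < 4 * max(spacing))) {
    stop_pahemo(sprintf(
      "Vessel under-resolved: the smallest diameter (%.1f mm) spans fewer than 4 voxels at %.1f mm spacing.",
      min(2 * radii * 1000), max(spacing)
    ), class = "pahemo_resolution_error")
  }
  sp_m <- spacing / 1000
  # world extents (m) with padding
  pad <- 2 * max(sp_m)
  ends <- lapply(limbs, function(l) {
    ax <- rbind(l$A, l$A + l$d * l$len)
    rbind(apply(ax, 2, min) - l$radius, apply(ax, 2, max) + l$radius)
  })
  pts <- do.call(rbind, ends)
  lo <- apply(pts, 2, min) - pad
  hi <- apply(pts, 2, max) + pad
  lo[3] <- 0  # flat inlet face at z = 0
  dims <- pmax(ceiling((hi - lo) / sp_m), 4L)
  coords <- lapply(1:3, function(a) lo[a] + (seq_len(dims[a]) - 0.5) * sp_m[a])
  grid <- as.matrix(expand.grid(x = coords[[1]], y = coords[[2]], z = coords[[3]],
                                KEEP.OUT.ATTRS = FALSE))
  lab <- phantom_label_points(grid, limbs)
  labels <- array(lab, dim = dims)
  mask <- labels > 0L

  origin_mm <- (lo + 0.5 * sp_m) * 1000
  inlet_z <- min(2.5 * sp_m[3], 0.2 * limbs$mpa$len)
  inlet <- analysis_plane(c(0, 0, inlet_z) * 1000, c(0, 0, 1))
  outlets <- if (length(limbs) == 3L) {
    lapply(limbs[c("lpa", "rpa")], function(l) {
      analysis_plane((l$A + 0.7 * l$len * l$d) * 1000, l$d)
    })
  } else {
    list(mpa = analysis_plane(c(0, 0, 0.9 * limbs$mpa$len) * 1000, c(0, 0, 1)))
  }
  structure(
    list(mask = mask, labels = labels, spacing = spacing, origin = origin_mm,
         inlet_plane = inlet, outlet_planes = outlets,
         meta = list(spec = spec, limbs = limbs)),
    class = "vessel_geometry"
  )
}

#' @export
print.vessel_geometry <- function(x, ...) {
  cat(sprintf(
    "<vessel_geometry> %s voxels at (%.2g, %.2g, %.2g) mm; %d lumen voxels (MPA %d, LPA %d, RPA %d)\n",
    paste(dim(x$mask), collapse = " x "),
    x$spacing[1], x$spacing[2], x$spacing[3],
    sum(x$mask), sum(x$labels == 1L), sum(x$labels == 2L), sum(x$labels == 3L)
  ))
  invisible(x)
}

# Flow harmonics for each limb: the branch waveforms are the inlet waveform
# scaled by the prescribed split (frequency-independent division of flow).
phantom_harmonics <- function(spec) {
  wf <- spec$waveform
  if (is.null(wf)) {
    wf <- half_sine_waveform(spec$stroke_volume_ml, spec$period,
                             spec$systole_fraction)
  } else {
    sv <- stroke_volume(wf)
    wf <- flow_waveform(wf$time, wf$flow * spec$stroke_volume_ml / sv,
                        wf_period(wf))
  }
  h <- flow_harmonics(wf, spec$n_harmonics)
  list(
    mpa = h,
    lpa = structure(h * (1 - spec$rpa_fraction), period = spec$period),
    rpa = structure(h * spec$rpa_fraction, period = spec$period),
    waveform = wf
  )
}

# Fine-grid interpolator for the per-limb Womersley radial shapes; returns a
# function(rho) -> complex shape matrix.  Linear interpolation on a 1024-knot
# radial grid keeps Bessel evaluations O(1) per limb.
womersley_shape_interp <- function(harmonics, radius, nu, period, n_knots = 1024L) {
  rg <- seq(0, radius, length.out = n_knots)
  sh <- womersley_radial_shapes(rg, harmonics, radius, nu, period)
  function(rho) {
    xi <- pmin(pmax(rho, 0), radius) / radius * (n_knots - 1L) + 1
    i0 <- pmin(floor(xi), n_knots - 1L)
    wgt <- xi - i0
    sh[i0, , drop = FALSE] * (1 - wgt) + sh[i0 + 1L, , drop = FALSE] * wgt
  }
}

# Peak analytic velocity over all limbs (for the VENC check).
phantom_peak_velocity <- function(spec) {
  limbs <- phantom_limbs(spec)
  hs <- phantom_harmonics(spec)
  tt <- seq(0, spec$period, length.out = 201L)
  peak <- 0
  for (l in limbs) {
    h <- hs[[l$name]]
    u <- womersley_velocity(seq(0, l$radius, length.out = 101L), tt, h,
                            l$radius, spec$nu, spec$period)
    peak <- max(peak, max(abs(u)))
  }
  peak
}

#' Generate a synthetic 4D-flow MRI study
#'
#' Samples the phantom's analytic Womersley velocity field at voxel centres
#' over `n_frames` cardiac frames.  Voxels near the lumen wall are
#' partial-volume averaged (mean of 27 sub-samples, with zero velocity
#' outside the lumen), reproducing the near-wall signal dilution of real
#' phase-contrast data.  Optional zero-mean Gaussian noise is added to the
#' three velocity components, and velocities are clipped at the
#' velocity-encoding limit.
#'
#' @param spec a [phantom_spec()].
#' @param geometry optional [generate_bifurcation_geometry()] result; must
#'   share `spacing` if supplied.
#' @param n_frames number of cardiac frames (>= 10, default 25).
#' @param spacing voxel spacing (mm).
#' @return a `flow_study`: list with `magnitude` (array `nx,ny,nz,F`),
#'   `velocity` (list of arrays `vx`, `vy`, `vz`, m/s), `spacing`, `origin`,
#'   `frame_times`, `period`, `venc` and `meta`.
#' @export
generate_flow_study <- function(spec, geometry = NULL, n_frames = 25L,
                                spacing = c(2, 2.5, 2.5)) {
  if (n_frames < 10L) stop_pahemo("At least 10 cardiac frames are required.")
  if (is.null(geometry)) {
    geometry <- generate_bifurcation_geometry(spec, spacing)
  } else if (max(abs(geometry$spacing - spacing)) > 1e-9) {
    stop_pahemo("`geometry` spacing does not match the requested study spacing.")
  }
  peak <- phantom_peak_velocity(spec)
  if (peak > spec$venc) {
    stop_pahemo(sprintf(
      "Analytic peak velocity %.2f m/s exceeds VENC %.2f m/s; aliasing is not modelled.",
      peak, spec$venc
    ), class = "pahemo_venc_error")
  }
  limbs <- geometry$meta$limbs
  hs <- phantom_harmonics(spec)
  frame_times <- seq(0, spec$period, length.out = n_frames + 1L)[seq_len(n_frames)]
  dims <- dim(geometry$mask)
  sp_m <- geometry$spacing / 1000
  coords <- lapply(1:3, function(a) {
    geometry$origin[a] / 1000 + (seq_len(dims[a]) - 1) * sp_m[a]
  })
  grid <- as.matrix(expand.grid(x = coords[[1]], y = coords[[2]], z = coords[[3]],
                                KEEP.OUT.ATTRS = FALSE))
  nvox <- nrow(grid)

  # wall-adjacent voxels (within half a voxel diagonal of any limb wall)
  # are partial-volume averaged over a 3 x 3 x 3 sub-grid
  halfdiag <- 0.5 * sqrt(sum(sp_m^2))
  near_wall <- rep(FALSE, nvox)
  for (l in limbs) {
    co <- limb_coords(grid, l)
    near_wall <- near_wall | (abs(co$rho - l$radius) <= halfdiag &
                                co$s_clamped >= -halfdiag &
                                co$s <= l$len + halfdiag)
  }

  vx <- matrix(0, nvox, n_frames)
  vy <- matrix(0, nvox, n_frames)
  vz <- matrix(0, nvox, n_frames)
  lumen_frac <- as.numeric(geometry$labels > 0L)

  interp <- lapply(limbs, function(l) {
    womersley_shape_interp(hs[[l$name]], l$radius, spec$nu, spec$period)
  })
  ph <- exp(1i * outer(seq_along(hs$mpa) - 1L, frame_times) * 2 * pi / spec$period)

  add_limb_velocity <- function(points, rows, weight) {
    lab <- phantom_label_points(points, limbs)
    for (k in seq_along(limbs)) {
      l <- limbs[[k]]
      idx <- which(lab == if (length(limbs) == 1L) 1L else k)
      if (!length(idx)) next
      co <- limb_coords(points[idx, , drop = FALSE], l)
      u <- Re(interp[[k]](co$rho) %*% ph)      # n_idx x F
      r <- rows[idx]
      vx[r, ] <<- vx[r, ] + weight * u * l$d[1]
      vy[r, ] <<- vy[r, ] + weight * u * l$d[2]
      vz[r, ] <<- vz[r, ] + weight * u * l$d[3]
    }
    invisible(lab)
  }

  bulk <- which(!near_wall & geometry$labels > 0L)
  if (length(bulk)) add_limb_velocity(grid[bulk, , drop = FALSE], bulk, 1)

  pv <- which(near_wall)
  if (length(pv)) {
    offs <- as.matrix(expand.grid(a = (-1:1) / 3, b = (-1:1) / 3, c = (-1:1) / 3))
    offs <- sweep(offs, 2, sp_m, `*`)
    inside_count <- numeric(length(pv))
    for (o in seq_len(nrow(offs))) {
      pts <- sweep(grid[pv, , drop = FALSE], 2, offs[o, ], `+`)
      lab <- add_limb_velocity(pts, pv, 1 / nrow(offs))
      inside_count <- inside_count + (lab > 0L)
    }
    lumen_frac[pv] <- inside_count / nrow(offs)
  }

  if (spec$noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(spec$seed)
    vx <- vx + rnorm(length(vx), sd = spec$noise_sd)
    vy <- vy + rnorm(length(vy), sd = spec$noise_sd)
    vz <- vz + rnorm(length(vz), sd = spec$noise_sd)
  }
  clip <- function(v) pmin(pmax(v, -spec$venc), spec$venc)

  mag <- array(rep(5 + 95 * lumen_frac, n_frames), dim = c(dims, n_frames))
  structure(
    list(
      magnitude = mag,
      velocity = list(
        vx = array(clip(vx), dim = c(dims, n_frames)),
        vy = array(clip(vy), dim = c(dims, n_frames)),
        vz = array(clip(vz), dim = c(dims, n_frames))
      ),
      spacing = geometry$spacing, origin = geometry$origin,
      frame_times = frame_times, period = spec$period, venc = spec$venc,
      meta = list(spec = spec, waveform = hs$waveform, harmonics = hs)
    ),
    class = "flow_study"
  )
}

#' @export
print.flow_study <- function(x, ...) {
  cat(sprintf(
    "<flow_study> %s voxels x %d frames, period %.2f s, venc %.1f m/s\n",
    paste(dim(x$magnitude)[1:3], collapse = " x "),
    length(x$frame_times), x$period, x$venc
  ))
  invisible(x)
}

# Save/restore the RNG state so seeded generation does not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
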