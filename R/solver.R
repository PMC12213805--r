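#' Solver configuration
#'
#' Run-control parameters of the pulsatile tube solver.  The defaults follow
#' the simulation protocol the package reproduces: a 0.005 s time step and a
#' minimum of three cardiac cycles, continuing until the cycle-to-cycle
#' variation of the outlet pressure drops below 1%.
#'
#' @param dt time step (s), default 0.005 (snapped so a cycle is an integer
#'   number of steps).
#' @param n_cycles_min minimum number of cardiac cycles (>= 3).
#' @param n_cycles_max maximum number of cycles before giving up.
#' @param periodicity_tol cycle-to-cycle variation tolerance (%), default 1.
#' @param nr,nz radial and axial cell counts (defaults 32 x 48; at least
#'   16 x 32 is recommended for quantitative use).
#' @param rho blood density (kg/m^3), default 1060.
#' @param theta implicitness of the viscous terms (0.5 = Crank-Nicolson,
#'   1 = backward Euler), default 0.5.
#' @param n_harmonics harmonics used when the inlet is a flow waveform.
#' @return a list of class `solver_config`.
#' @export
solver_config <- function(dt = 0.005, n_cycles_min = 3L, n_cycles_max = 10L,
                          periodicity_tol = 1, nr = 32L, nz = 48L,
                          rho = 1060, theta = 0.5, n_harmonics = 10L) {
  if (dt <= 0) stop_pahemo("`dt` must be positive.")
  if (n_cycles_min < 3L) stop_pahemo("At least three cycles are required.")
  if (nr < 4L || nz < 4L) stop_pahemo("Grid resolution is too coarse.")
  structure(
    list(dt = dt, n_cycles_min = as.integer(n_cycles_min),
         n_cycles_max = as.integer(n_cycles_max),
         periodicity_tol = periodicity_tol, nr = as.integer(nr),
         nz = as.integer(nz), rho = rho, theta = theta,
         n_harmonics = as.integer(n_harmonics)),
    class = "solver_config"
  )
}

#' Assess the laminar-flow assumption
#'
#' Computes the peak Reynolds number `Re = rho U D / mu`, the Womersley
#' number `alpha = (D/2) sqrt(2 pi rho / (mu T))`, and applies the empirical
#' transition criterion for large pulsatile arteries: flow is taken as
#' laminar when `Re_peak < 150 * alpha`.
#'
#' @param peak_velocity peak cross-sectional velocity (m/s).
#' @param diameter vessel diameter (m).
#' @param rho density (kg/m^3), default 1060.
#' @param mu_ref reference dynamic viscosity (Pa s); the high-shear limit is
#'   appropriate for peak flow.
#' @param period cardiac cycle length (s).
#' @return a tibble with `re_peak`, `alpha`, `critical` (`150 * alpha`) and
#'   `laminar`.
#' @examples
#' assess_flow_regime(0.2, 0.03, 1060, 3.5e-3, 0.8)
#' @export
assess_flow_regime <- function(peak_velocity, diameter, rho = 1060,
                               mu_ref, period) {
  if (any(c(diameter, rho, mu_ref, period) <= 0) || peak_velocity < 0) {
    stop_pahemo("All regime inputs must be positive (velocity non-negative).")
  }
  re <- rho * peak_velocity * diameter / mu_ref
  alpha <- (diameter / 2) * sqrt(2 * pi * rho / (mu_ref * period))
  tibble(re_peak = re, alpha = alpha, critical = 150 * alpha,
         laminar = re < 150 * alpha)
}

# Radially bin an inlet_profile into an axisymmetric profile on radial cell
# centres; returns a function(t) -> length(nr) velocities (periodic linear
# interpolation in time).
axisymmetrize_profile <- function(profile, r_centers, radius) {
  ctr <- profile$plane$origin
  rel <- sweep(profile$points, 2, ctr)
  rho <- sqrt(rowSums(rel^2)) / 1000  # mm -> m
  dr <- r_centers[2] - r_centers[1]
  bin <- pmin(pmax(floor(rho / dr) + 1L, 1L), length(r_centers))
  nf <- ncol(profile$velocity)
  prof <- matrix(0, length(r_centers), nf)
  for (b in unique(bin)) {
    prof[b, ] <- colMeans(profile$velocity[bin == b, , drop = FALSE])
  }
  # fill empty outer bins with zero (wall) and empty inner bins by nearest
  filled <- tabulate(bin, nbins = length(r_centers)) > 0
  for (i in which(!filled)) {
    near <- which(filled)[which.min(abs(which(filled) - i))]
    prof[i, ] <- prof[near, ]
  }
  tt <- profile$frame_times
  period <- profile$period
  function(t) {
    tm <- t %% period
    apply(prof, 1, function(row) {
      approx(c(tt, tt[1] + period), c(row, row[1]), xout = tm, rule = 2)$y
    })
  }
}

#' Simulate pulsatile generalized-Newtonian flow in a straight tube
#'
#' Solves the incompressible axisymmetric momentum and continuity equations
#' on a staggered (r, z) grid with an incremental pressure-projection
#' (fractional-step) scheme: explicit first-order upwind convection,
#' theta-implicit viscous terms with the shear-rate-dependent Quemada
#' viscosity evaluated from the previous step, rigid no-slip wall, a
#' prescribed inlet velocity profile (Womersley-reconstructed from a flow
#' waveform, or an axisymmetrized measured profile), and an outlet pressure
#' supplied every step by a coupled three-element Windkessel.  Cycles are
#' repeated until the outlet pressure is periodic (cycle-to-cycle variation
#' below the configured tolerance) or `n_cycles_max` is reached.
#'
#' @param radius tube radius (m).
#' @param length tube length (m).
#' @param inlet a [flow_waveform()] or an `inlet_profile`.
#' @param rheology a [rheology_params()] (use [newtonian_params()] for a
#'   constant viscosity).
#' @param outlet a [windkessel_params()].
#' @param config a [solver_config()].
#' @return a `tube_run`: list with the final two simulated cycles
#'   (`w`, `v`, `p` arrays over the cycle), wall shear-rate trace, outlet
#'   pressure/flow histories, the per-cycle periodicity log, the flow-regime
#'   report and grid metadata.  Pass it to [converged_final_cycle()] to
#'   obtain the final-cycle `hemo_field`.
#' @export
simulate_pulsatile_tube <- function(radius, length, inlet, rheology, outlet,
                                    config = solver_config()) {
  nr <- config$nr; nz <- config$nz
  rho <- config$rho; theta <- config$theta
  dr <- radius / nr; dz <- length / nz
  r_c <- (seq_len(nr) - 0.5) * dr
  r_f <- seq(0, nr) * dr

  mu_inf <- unname(viscosity_bounds(rheology)["mu_inf"])
  if (inherits(inlet, "flow_waveform")) {
    period <- wf_period(inlet)
    h <- flow_harmonics(inlet, config$n_harmonics)
    shapes <- womersley_radial_shapes(r_c, h, radius, mu_inf / rho, period)
    inlet_fn <- function(t) {
      drop(womersley_eval(shapes, t, period))
    }
  } else if (inherits(inlet, "inlet_profile")) {
    period <- inlet$period
    inlet_fn <- axisymmetrize_profile(inlet, r_c, radius)
  } else {
    stop_pahemo("`inlet` must be a flow_waveform or an inlet_profile.")
  }

  # advective stability: the convection step is explicit, so the internal
  # step is reduced below the configured dt when the CFL limit demands it
  u_scan <- vapply(seq(0, period, length.out = 101L), function(t) {
    max(abs(inlet_fn(t)))
  }, numeric(1))
  u_peak <- max(u_scan)
  dt_cfl <- if (u_peak > 0) 0.45 * dz / u_peak else Inf
  n_per <- max(round(period / min(config$dt, dt_cfl)), 50L)
  dt <- period / n_per

  # precompute one cycle of inlet profiles at the step grid
  w_in_cycle <- vapply(seq_len(n_per), function(k) inlet_fn((k - 1) * dt),
                       numeric(nr))
  # the inlet is ramped up smoothly over the first half cycle to avoid an
  # impulsive start from rest; all analysed cycles see the full waveform
  inlet_at <- function(step) {
    ramp <- min(1, (step - 1L) * dt / (0.5 * period))
    ramp * w_in_cycle[, ((step - 1L) %% n_per) + 1L]
  }
  q_of_profile <- function(wi) sum(2 * pi * r_c * wi) * dr
  regime <- assess_flow_regime(max(u_peak, 1e-12), 2 * radius, rho, mu_inf,
                               period)
  if (!regime$laminar) {
    warn("Peak Reynolds number exceeds the 150*alpha transition criterion; results assume laminar flow.")
  }

  # state
  w <- matrix(0, nr, nz + 1L)   # axial velocity at z-faces
  v <- matrix(0, nr + 1L, nz)   # radial velocity at r-faces
  p <- matrix(0, nr, nz)        # pressure at cell centres
  pc <- 0                       # Windkessel capacitor pressure

  newtonian <- rheology$hematocrit == 0

  # --- constant-coefficient pressure Poisson operator (Neumann, pinned) ---
  ip <- function(i, j) i + (j - 1L) * nr
  idx <- expand.grid(i = seq_len(nr), j = seq_len(nz))
  ii <- idx$i; jj <- idx$j
  cup <- ifelse(ii < nr, r_f[ii + 1L] / (r_c[ii] * dr^2), 0)
  cdn <- ifelse(ii > 1L, r_f[ii] / (r_c[ii] * dr^2), 0)
  czu <- ifelse(jj < nz, 1 / dz^2, 0)
  czd <- ifelse(jj > 1L, 1 / dz^2, 0)
  rows <- c(ip(ii, jj), ip(ii, jj)[ii < nr], ip(ii, jj)[ii > 1L],
            ip(ii, jj)[jj < nz], ip(ii, jj)[jj > 1L])
  cols <- c(ip(ii, jj), ip(ii + 1L, jj)[ii < nr], ip(ii - 1L, jj)[ii > 1L],
            ip(ii, jj + 1L)[jj < nz], ip(ii, jj - 1L)[jj > 1L])
  vals <- c(-(cup + cdn + czu + czd), cup[ii < nr], cdn[ii > 1L],
            czu[jj < nz], czd[jj > 1L])
  # pin cell (1,1) to fix the Neumann null space
  pin <- rows == 1L
  vals[pin] <- ifelse(cols[pin] == 1L, 1, 0)
  A_pois <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                                 dims = c(nr * nz, nr * nz))
  lu_pois <- Matrix::lu(A_pois)

  # corner-averaged viscosity (r-faces x z-faces) from cell-centre field
  corner_mu <- function(mu) {
    mup <- mu[c(1, seq_len(nr), nr), c(1, seq_len(nz), nz)]  # clamped pad
    0.25 * (mup[seq_len(nr + 1L), seq_len(nz + 1L)] +
              mup[seq_len(nr + 1L) + 1L, seq_len(nz + 1L)] +
              mup[seq_len(nr + 1L), seq_len(nz + 1L) + 1L] +
              mup[seq_len(nr + 1L) + 1L, seq_len(nz + 1L) + 1L])
  }

  shear_rate_field <- function(w, v) {
    w_cen <- 0.5 * (w[, seq_len(nz)] + w[, seq_len(nz) + 1L])
    dwdz <- (w[, seq_len(nz) + 1L] - w[, seq_len(nz)]) / dz
    dvdr <- (v[seq_len(nr) + 1L, ] - v[seq_len(nr), ]) / dr
    v_cen <- 0.5 * (v[seq_len(nr) + 1L, ] + v[seq_len(nr), ])
    e_tt <- v_cen / r_c
    wg <- rbind(w_cen[1, ], w_cen, -w_cen[nr, ])  # axis mirror, wall ghost
    dwdr <- (wg[seq_len(nr) + 2L, ] - wg[seq_len(nr), ]) / (2 * dr)
    vg <- cbind(v_cen[, 1], v_cen, v_cen[, nz])
    dvdz <- (vg[, seq_len(nz) + 2L] - vg[, seq_len(nz)]) / (2 * dz)
    erz <- 0.5 * (dwdr + dvdz)
    sqrt(2 * (dvdr^2 + e_tt^2 + dwdz^2) + 4 * erz^2)
  }

  # viscous operators applied to full fields (explicit part)
  visc_w_apply <- function(w, mu_c, mu_k) {
    out <- matrix(0, nr, nz + 1L)
    j <- 2:nz
    wi <- w[, j, drop = FALSE]
    up <- rbind(w[-1, j, drop = FALSE], 0)        # w[i+1], wall value 0
    dn <- rbind(0, w[-nr, j, drop = FALSE])       # w[i-1] (i=1 row unused)
    muk <- mu_k[, j, drop = FALSE]                # corners at z-face j
    c_up <- (r_f[-1] * muk[-1, , drop = FALSE]) / (r_c * dr^2)
    c_dn <- (r_f[seq_len(nr)] * muk[seq_len(nr), , drop = FALSE]) / (r_c * dr^2)
    rad <- c_up * (up - wi) + c_dn * (dn - wi)
    # wall face: one-sided second-order gradient through the no-slip wall
    c_wall <- (r_f[nr + 1L] * muk[nr + 1L, ]) / (r_c[nr] * dr^2)
    rad[nr, ] <- c_dn[nr, ] * (dn[nr, ] - wi[nr, ]) +
      c_wall * (-3 * wi[nr, ] + wi[nr - 1L, ] / 3)
    c_zu <- mu_c[, j, drop = FALSE] / dz^2
    c_zd <- mu_c[, j - 1L, drop = FALSE] / dz^2
    ax <- c_zu * (w[, j + 1L, drop = FALSE] - wi) +
      c_zd * (w[, j - 1L, drop = FALSE] - wi)
    out[, j] <- rad + ax
    out
  }

  visc_v_apply <- function(v, mu_c, mu_k) {
    out <- matrix(0, nr + 1L, nz)
    i <- 2:nr
    vi <- v[i, , drop = FALSE]
    c_up <- (r_c[i] * mu_c[i, , drop = FALSE]) / (r_f[i] * dr^2)
    c_dn <- (r_c[i - 1L] * mu_c[i - 1L, , drop = FALSE]) / (r_f[i] * dr^2)
    rad <- c_up * (v[i + 1L, , drop = FALSE] - vi) +
      c_dn * (v[i - 1L, , drop = FALSE] - vi)
    muk <- mu_k[i, seq_len(nz), drop = FALSE]      # corners (r_f[i], z_f[j])
    muk_up <- mu_k[i, -1, drop = FALSE]            # z_f[j+1]
    c_zu <- muk_up / dz^2
    c_zu[, nz] <- 0                                # outlet Neumann
    c_zd <- muk / dz^2
    c_zd[, 1] <- 2 * muk[, 1] / dz^2               # inlet Dirichlet v = 0
    v_up <- cbind(vi[, -1, drop = FALSE], vi[, nz])
    v_dn <- cbind(0 * vi[, 1], vi[, -nz, drop = FALSE])
    ax <- c_zu * (v_up - vi) + c_zd * (v_dn - vi)
    mu_vf <- 0.5 * (mu_c[i, , drop = FALSE] + mu_c[i - 1L, , drop = FALSE])
    out[i, ] <- rad + ax - mu_vf * vi / r_f[i]^2
    out
  }

  # implicit viscous matrices (rebuilt when the viscosity field changes)
  build_Aw <- function(mu_c, mu_k) {
    j <- rep(2:nz, each = nr)
    i <- rep(seq_len(nr), nz - 1L)
    n_unk <- nr * (nz - 1L)
    id <- function(i, j) i + (j - 2L) * nr
    muk_up <- mu_k[cbind(i + 1L, j)]
    muk_dn <- mu_k[cbind(i, j)]
    c_up <- r_f[i + 1L] * muk_up / (r_c[i] * dr^2)
    wall <- i == nr
    # wall rows: one-sided second-order no-slip gradient -> 3c on the
    # diagonal and an extra c/3 coupling to the first interior neighbour
    c_wall <- r_f[nr + 1L] * muk_up[wall] / (r_c[nr] * dr^2)
    c_up[wall] <- 3 * c_wall
    c_dn <- r_f[i] * muk_dn / (r_c[i] * dr^2)
    c_dn_off <- c_dn
    c_dn_off[wall] <- c_dn[wall] + c_wall / 3
    c_zu <- mu_c[cbind(i, j)] / dz^2
    c_zu[j == nz] <- 0                             # outlet Neumann folded
    c_zd <- mu_c[cbind(i, j - 1L)] / dz^2
    diagc <- 1 + dt * theta / rho * (c_up + c_dn + c_zu + c_zd)
    # note: c_up at the wall row acts only on the diagonal (w = 0 beyond)
    sel_up <- i < nr; sel_dn <- i > 1L; sel_zu <- j < nz; sel_zd <- j > 2L
    rows <- c(id(i, j), id(i, j)[sel_up], id(i, j)[sel_dn],
              id(i, j)[sel_zu], id(i, j)[sel_zd])
    cols <- c(id(i, j), id(i + 1L, j)[sel_up], id(i - 1L, j)[sel_dn],
              id(i, j + 1L)[sel_zu], id(i, j - 1L)[sel_zd])
    vals <- c(diagc,
              -dt * theta / rho * c_up[sel_up],
              -dt * theta / rho * c_dn_off[sel_dn],
              -dt * theta / rho * c_zu[sel_zu],
              -dt * theta / rho * c_zd[sel_zd])
    list(A = Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                                  dims = c(n_unk, n_unk)),
         c_zd_inlet = c_zd[j == 2L])
  }

  build_Av <- function(mu_c, mu_k) {
    i <- rep(2:nr, nz)
    j <- rep(seq_len(nz), each = nr - 1L)
    n_unk <- (nr - 1L) * nz
    id <- function(i, j) (i - 1L) + (j - 1L) * (nr - 1L)
    c_up <- r_c[i] * mu_c[cbind(i, j)] / (r_f[i] * dr^2)
    c_dn <- r_c[i - 1L] * mu_c[cbind(i - 1L, j)] / (r_f[i] * dr^2)
    c_zu <- mu_k[cbind(i, j + 1L)] / dz^2
    c_zu[j == nz] <- 0
    c_zd <- mu_k[cbind(i, j)] / dz^2
    c_zd[j == 1L] <- 2 * c_zd[j == 1L]
    mu_vf <- 0.5 * (mu_c[cbind(i, j)] + mu_c[cbind(i - 1L, j)])
    diagc <- 1 + dt * theta / rho *
      (c_up + c_dn + c_zu + c_zd + mu_vf / r_f[i]^2)
    sel_up <- i < nr; sel_dn <- i > 2L; sel_zu <- j < nz; sel_zd <- j > 1L
    rows <- c(id(i, j), id(i, j)[sel_up], id(i, j)[sel_dn],
              id(i, j)[sel_zu], id(i, j)[sel_zd])
    cols <- c(id(i, j), id(i + 1L, j)[sel_up], id(i - 1L, j)[sel_dn],
              id(i, j + 1L)[sel_zu], id(i, j - 1L)[sel_zd])
    vals <- c(diagc,
              -dt * theta / rho * c_up[sel_up],
              -dt * theta / rho * c_dn[sel_dn],
              -dt * theta / rho * c_zu[sel_zu],
              -dt * theta / rho * c_zd[sel_zd])
    Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(n_unk, n_unk))
  }

  adv_w <- function(w, v) {
    out <- matrix(0, nr, nz + 1L)
    j <- 2:nz
    wi <- w[, j, drop = FALSE]
    ddz_up <- (wi - w[, j - 1L, drop = FALSE]) / dz
    ddz_dn <- (w[, j + 1L, drop = FALSE] - wi) / dz
    out[, j] <- ifelse(wi >= 0, wi * ddz_up, wi * ddz_dn)
    vbar <- 0.25 * (v[seq_len(nr), j - 1L, drop = FALSE] +
                      v[seq_len(nr) + 1L, j - 1L, drop = FALSE] +
                      v[seq_len(nr), j, drop = FALSE] +
                      v[seq_len(nr) + 1L, j, drop = FALSE])
    wg_up <- rbind(w[-1, j, drop = FALSE], -w[nr, j])   # wall ghost
    wg_dn <- rbind(w[1, j], w[-nr, j, drop = FALSE])    # axis mirror
    ddr_up <- (wi - wg_dn) / dr
    ddr_dn <- (wg_up - wi) / dr
    out[, j] <- out[, j] + ifelse(vbar >= 0, vbar * ddr_up, vbar * ddr_dn)
    out
  }

  adv_v <- function(w, v) {
    out <- matrix(0, nr + 1L, nz)
    i <- 2:nr
    vi <- v[i, , drop = FALSE]
    ddr_up <- (vi - v[i - 1L, , drop = FALSE]) / dr
    ddr_dn <- (v[i + 1L, , drop = FALSE] - vi) / dr
    out[i, ] <- ifelse(vi >= 0, vi * ddr_up, vi * ddr_dn)
    wbar <- 0.25 * (w[i - 1L, seq_len(nz), drop = FALSE] +
                      w[i, seq_len(nz), drop = FALSE] +
                      w[i - 1L, seq_len(nz) + 1L, drop = FALSE] +
                      w[i, seq_len(nz) + 1L, drop = FALSE])
    v_up <- cbind(vi[, -1, drop = FALSE], vi[, nz])
    v_dn <- cbind(0 * vi[, 1], vi[, -nz, drop = FALSE])
    ddz_up <- (vi - v_dn) / dz
    ddz_dn <- (v_up - vi) / dz
    out[i, ] <- out[i, ] + ifelse(wbar >= 0, wbar * ddz_up, wbar * ddz_dn)
    out
  }

  divergence <- function(w, v) {
    (sweep(v[-1, , drop = FALSE], 1, r_f[-1], `*`) -
       sweep(v[-(nr + 1L), , drop = FALSE], 1, r_f[seq_len(nr)], `*`)) /
      (r_c * dr) +
      (w[, -1, drop = FALSE] - w[, -(nz + 1L), drop = FALSE]) / dz
  }

  wk_step <- function(pc, q0, q1) {
    dp <- function(p, q) (q - (p - outlet$distal_pressure) / outlet$r2) / outlet$c
    qh <- 0.5 * (q0 + q1)
    k1 <- dp(pc, q0); k2 <- dp(pc + dt / 2 * k1, qh)
    k3 <- dp(pc + dt / 2 * k2, qh); k4 <- dp(pc + dt * k3, q1)
    pc + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }

  # history buffers for the final two cycles
  new_buf <- function() list(
    w = array(0, c(nr, nz + 1L, n_per)),
    v = array(0, c(nr + 1L, nz, n_per)),
    p = array(0, c(nr, nz, n_per)),
    wall_shear = matrix(0, nz + 1L, n_per),
    p_out = numeric(n_per), q_out = numeric(n_per)
  )
  prev_buf <- NULL; cur_buf <- new_buf()
  cycle_log <- tibble(cycle = integer(), periodicity_pct = numeric())
  max_div <- 0

  Aw_cache <- NULL; Av_cache <- NULL
  q_prev <- q_of_profile(inlet_at(1L))
  step <- 0L
  done <- FALSE
  cycle <- 0L
  while (!done) {
    cycle <- cycle + 1L
    for (k in seq_len(n_per)) {
      step <- step + 1L
      w_in_new <- inlet_at(step + 1L)   # t^{n+1}
      # CFL check on the explicit convection
      cfl <- max(max(abs(w)) * dt / dz, max(abs(v)) * dt / dr)
      if (cfl > 1) {
        stop_pahemo(sprintf(
          "CFL violation (%.2f) in the convection step at t = %.3f s.",
          cfl, step * dt
        ), class = "pahemo_solver_error")
      }
      gam <- shear_rate_field(w, v)
      mu_c <- matrix(quemada_viscosity(as.numeric(gam), rheology), nr, nz)
      mu_k <- corner_mu(mu_c)
      if (newtonian) {
        if (is.null(Aw_cache)) {
          Aw_cache <- build_Aw(mu_c, mu_k); Aw_cache$lu <- Matrix::lu(Aw_cache$A)
          Av_cache <- list(A = build_Av(mu_c, mu_k))
          Av_cache$lu <- Matrix::lu(Av_cache$A)
        }
        Aw <- Aw_cache; Av <- Av_cache
      } else {
        Aw <- build_Aw(mu_c, mu_k); Aw$lu <- Aw$A
        Av <- list(A = build_Av(mu_c, mu_k)); Av$lu <- Av$A
      }

      # --- predictor for w ---
      expl_w <- -adv_w(w, v) + (1 - theta) / rho * visc_w_apply(w, mu_c, mu_k)
      gpz <- matrix(0, nr, nz + 1L)
      gpz[, 2:nz] <- (p[, 2:nz] - p[, seq_len(nz - 1L)]) / dz
      rhs_w <- w[, 2:nz, drop = FALSE] +
        dt * (expl_w[, 2:nz, drop = FALSE] - gpz[, 2:nz, drop = FALSE] / rho)
      rhs_w[, 1] <- rhs_w[, 1] + dt * theta / rho * Aw$c_zd_inlet * w_in_new
      w_star <- w
      w_star[, 1] <- w_in_new
      w_star[, 2:nz] <- matrix(as.numeric(Matrix::solve(Aw$lu, as.numeric(rhs_w))),
                               nr, nz - 1L)
      w_star[, nz + 1L] <- w_star[, nz]
      # enforce global mass balance on the outlet face
      q_in <- q_of_profile(w_in_new)
      q_out_star <- q_of_profile(w_star[, nz + 1L])
      w_star[, nz + 1L] <- w_star[, nz + 1L] +
        (q_in - q_out_star) / (pi * radius^2)

      # --- predictor for v ---
      expl_v <- -adv_v(w, v) + (1 - theta) / rho * visc_v_apply(v, mu_c, mu_k)
      gpr <- matrix(0, nr + 1L, nz)
      gpr[2:nr, ] <- (p[2:nr, ] - p[seq_len(nr - 1L), ]) / dr
      rhs_v <- v[2:nr, , drop = FALSE] +
        dt * (expl_v[2:nr, , drop = FALSE] - gpr[2:nr, , drop = FALSE] / rho)
      v_star <- v
      v_star[2:nr, ] <- matrix(as.numeric(Matrix::solve(Av$lu, as.numeric(rhs_v))),
                               nr - 1L, nz)

      # --- pressure projection ---
      div <- divergence(w_star, v_star)
      rhs_p <- as.numeric(div) * rho / dt
      rhs_p[1] <- 0   # pinned cell
      phi <- matrix(as.numeric(Matrix::solve(lu_pois, rhs_p)), nr, nz)
      w <- w_star
      w[, 2:nz] <- w[, 2:nz] - dt / rho * (phi[, 2:nz] - phi[, seq_len(nz - 1L)]) / dz
      v <- v_star
      v[2:nr, ] <- v[2:nr, ] - dt / rho * (phi[2:nr, ] - phi[seq_len(nr - 1L), ]) / dr
      p <- p + phi
      if (any(!is.finite(w)) || any(!is.finite(v))) {
        stop_pahemo("Non-finite velocities after the projection step.",
                    class = "pahemo_solver_error")
      }
      max_div <- max(max_div, max(abs(divergence(w, v))))

      # --- Windkessel outlet coupling and pressure gauge ---
      q_out <- q_of_profile(w[, nz + 1L])
      pc <- wk_step(pc, q_prev, q_out)
      q_prev <- q_out
      p_out_target <- outlet$r1 * q_out + pc
      p <- p + (p_out_target - sum(p[, nz] * r_c) / sum(r_c))

      # record
      cur_buf$w[, , k] <- w
      cur_buf$v[, , k] <- v
      cur_buf$p[, , k] <- p
      cur_buf$q_out[k] <- q_out
      cur_buf$p_out[k] <- p_out_target
      # inward-normal wall shear rate: one-sided second-order difference
      # through the no-slip wall and the two nearest cell centres
      u1 <- w[nr, ]; u2 <- w[nr - 1L, ]
      cur_buf$wall_shear[, k] <- (9 * u1 - u2) / (3 * dr)
    }
    if (!is.null(prev_buf)) {
      met <- tryCatch(
        100 * max(abs(cur_buf$p_out - prev_buf$p_out)) /
          max(abs(cur_buf$p_out)),
        error = function(e) Inf
      )
      cycle_log <- dplyr::bind_rows(cycle_log,
                                    tibble(cycle = cycle, periodicity_pct = met))
      if (cycle >= config$n_cycles_min && met < config$periodicity_tol) {
        done <- TRUE
      }
    }
    if (cycle >= config$n_cycles_max) done <- TRUE
    if (!done) {
      tmp <- prev_buf
      prev_buf <- cur_buf
      cur_buf <- if (is.null(tmp)) new_buf() else tmp
    }
  }

  structure(
    list(
      final = cur_buf, previous = prev_buf,
      times = (seq_len(n_per) - 1L) * dt + dt,
      r_centers = r_c, z_faces = seq(0, nz) * dz, z_centers = (seq_len(nz) - 0.5) * dz,
      radius = radius, length = length, dt = dt, period = period,
      cycles_run = cycle, cycle_log = cycle_log, max_divergence = max_div,
      regime = regime, rheology = rheology, outlet = outlet, config = config,
      mu_inf = mu_inf
    ),
    class = "tube_run"
  )
}

#' @export
print.tube_run <- function(x, ...) {
  met <- if (nrow(x$cycle_log)) tail(x$cycle_log$periodicity_pct, 1) else NA_real_
  cat(sprintf(
    "<tube_run> %d x %d grid, %d cycles (dt = %.4g s), final periodicity %.3g%%\n",
    x$config$nr, x$config$nz, x$cycles_run, x$dt, met
  ))
  invisible(x)
}

#' Extract the converged final cycle of a tube run
#'
#' Validates that the run reached periodicity (cycle-to-cycle variation of
#' the outlet pressure below the configured tolerance) and returns the final
#' cycle as a `hemo_field` together with the achieved metric.
#'
#' @param run a `tube_run` from [simulate_pulsatile_tube()].
#' @return a `hemo_field`: list with velocity (`w`, `v`) and pressure
#'   arrays over the final cycle, the signed wall shear-rate trace
#'   (`wall_shear`, axial stations x time), grid coordinates, the achieved
#'   `periodicity_pct` and the flow-regime report.
#' @export
converged_final_cycle <- function(run) {
  if (is.null(run$previous)) {
    stop_pahemo("At least two complete cycles are required.")
  }
  met <- tail(run$cycle_log$periodicity_pct, 1)
  if (met >= run$config$periodicity_tol) {
    stop_pahemo(sprintf(
      "Run did not reach periodicity: %.2f%% variation after %d cycles (tolerance %.2f%%).",
      met, run$cycles_run, run$config$periodicity_tol
    ), class = "pahemo_convergence_error")
  }
  structure(
    list(
      w = run$final$w, v = run$final$v, p = run$final$p,
      wall_shear = run$final$wall_shear,
      p_out = run$final$p_out, q_out = run$final$q_out,
      times = run$times, r_centers = run$r_centers,
      z_faces = run$z_faces, z_centers = run$z_centers,
      radius = run$radius, length = run$length, period = run$period,
      periodicity_pct = met, regime = run$regime,
      rheology = run$rheology, mu_inf = run$mu_inf,
      max_divergence = run$max_divergence
    ),
    class = "hemo_field"
  )
}

#' @export
print.hemo_field <- function(x, ...) {
  cat(sprintf(
    "<hemo_field> final cycle: %d x %d grid x %d steps, periodicity %.3g%%\n",
    length(x$r_centers), length(x$z_centers), length(x$times),
    x$periodicity_pct
  ))
  invisible(x)
}
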