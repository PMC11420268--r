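# Incompressible Newtonian laminar flow on the voxel grid.
#
# Fractional-step (projection) scheme: explicit upwind advection and explicit
# central diffusion on cell-centred velocities, then a pressure projection
# that zeroes the divergence of the face volume fluxes (measured on the faces
# between fluid cells and at boundary faces) to linear-solver accuracy. The
# pressure Poisson matrix is factorized once per grid (sparse Cholesky) and
# reused every step. Geometry is mm; the solver works in SI (m, s, Pa).

#' Blood properties
#' @param density kg/m^3
#' @param viscosity dynamic viscosity, Pa.s
#' @return object of class `fluid_properties`
#' @export
fluid_properties <- function(density = 1060, viscosity = 0.0035) {
  stopifnot(density > 0, viscosity > 0)
  structure(list(density = density, viscosity = viscosity,
                 nu = viscosity / density), class = "fluid_properties")
}

#' Atrial-fibrillation pulmonary-vein inflow waveform
#'
#' Sum of two raised-cosine pulses per cycle -- the systolic (S) and early
#' diastolic (D) waves -- on a small baseline, with no atrial-contraction (A)
#' wave, as in atrial fibrillation. Velocity is in m/s and never negative.
#' Amplitudes are calibrated so that region-of-interest mean velocities in
#' the default anatomy fall in the 0.04--0.07 m/s range.
#'
#' @param period cycle period (s)
#' @param s_amp,s_phase,s_width S-wave amplitude (m/s), peak phase and
#'   half-width (fractions of the cycle)
#' @param d_amp,d_phase,d_width D-wave parameters
#' @param baseline baseline velocity (m/s)
#' @param per_pv_scale length-4 multiplier per pulmonary vein
#' @return object of class `af_waveform`; call it as a function of time
#' @export
af_waveform <- function(period = 1.01,
                        s_amp = 0.36, s_phase = 0.13, s_width = 0.20,
                        d_amp = 0.45, d_phase = 0.55, d_width = 0.28,
                        baseline = 0.09, per_pv_scale = c(1, 1, 1, 1)) {
  stopifnot(period > 0, s_amp >= 0, d_amp >= 0, baseline >= 0)
  w <- structure(list(period = period, s_amp = s_amp, s_phase = s_phase,
                      s_width = s_width, d_amp = d_amp, d_phase = d_phase,
                      d_width = d_width, baseline = baseline,
                      per_pv_scale = per_pv_scale), class = "af_waveform")
  w
}

#' Evaluate an AF waveform
#' @param waveform an `af_waveform`
#' @param t time(s) in s
#' @return inflow velocity (m/s), periodic in the cycle period
#' @export
waveform_velocity <- function(waveform, t) {
  ph <- (t / waveform$period) %% 1
  pulse <- function(amp, center, width) {
    # phase distance wrapped on the cycle circle
    dx <- pmin(abs(ph - center), 1 - abs(ph - center)) / width
    ifelse(dx <= 1, amp * 0.5 * (1 + cos(pi * dx)), 0)
  }
  waveform$baseline +
    pulse(waveform$s_amp, waveform$s_phase, waveform$s_width) +
    pulse(waveform$d_amp, waveform$d_phase, waveform$d_width)
}

#' Solver settings
#'
#' @param dt time step (s)
#' @param warmup_cycles cycles run before evaluation (flow spin-up)
#' @param eval_cycles cycles recorded for marker evaluation
#' @param save_stride record every n-th step
#' @param max_cfl advective CFL cap; steps exceeding it are sub-stepped
#' @param convergence_tol divergence residual tolerance (1/s) for the
#'   projected velocity field
#' @return object of class `solver_settings`
#' @export
solver_settings <- function(dt = 0.005, warmup_cycles = 10, eval_cycles = 6,
                            save_stride = 2, max_cfl = 0.7, convergence_tol = 1e-8) {
  stopifnot(dt > 0, eval_cycles >= 1, max_cfl > 0, convergence_tol > 0)
  structure(list(dt = dt, warmup_cycles = warmup_cycles,
                 eval_cycles = eval_cycles, save_stride = save_stride,
                 max_cfl = max_cfl, convergence_tol = convergence_tol),
            class = "solver_settings")
}

# ---- discrete operators ----------------------------------------------------

#' Build the discrete flow operators for a grid
#'
#' Face pair lists, boundary-face groups and the factorized pressure Poisson
#' operator. Called once per scenario; the result is reused every time step.
#'
#' @param grid an `laa_grid`
#' @return an opaque `laa_flow_ops` object
#' @export
build_flow_ops <- function(grid) {
  hm <- grid$h / 1000
  n <- grid$n_fluid
  nbr <- grid$nbr
  # interior face pair lists per axis (+x, +y, +z owners)
  fpairs <- lapply(c(1L, 3L, 5L), function(d) {
    i <- which(nbr[, d] > 0L)
    list(i = i, j = nbr[i, d])
  })
  names(fpairs) <- c("x", "y", "z")

  bf <- grid$bfaces
  bgroups <- split(seq_len(nrow(bf)), bf$dir)

  # pressure Poisson: A p = -div(U*)/dt, Neumann at walls/inlets/symmetry,
  # Dirichlet p = 0 at outlet faces (half-cell), SPD
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  diag_acc <- numeric(n)
  for (ax in c("x", "y", "z")) {
    fp <- fpairs[[ax]]
    if (!length(fp$i)) next
    ii <- c(ii, fp$i, fp$j)
    jj <- c(jj, fp$j, fp$i)
    xx <- c(xx, rep(-1, 2 * length(fp$i)))
    tab_i <- tabulate(fp$i, n); tab_j <- tabulate(fp$j, n)
    diag_acc <- diag_acc + tab_i + tab_j
  }
  out_faces <- which(bf$bc_type == "outlet")
  if (length(out_faces)) {
    tb <- tabulate(bf$cell[out_faces], n)
    diag_acc <- diag_acc + 2 * tb
  }
  pinned <- length(out_faces) == 0L
  if (pinned) diag_acc[1] <- diag_acc[1] + 1  # fix the pressure level
  A <- Matrix::sparseMatrix(i = c(ii, seq_len(n)), j = c(jj, seq_len(n)),
                            x = c(xx, diag_acc) / hm^2, dims = c(n, n))
  chol <- Matrix::Cholesky(methods::as(A, "symmetricMatrix"), LDL = FALSE)

  structure(list(
    grid = grid, hm = hm, n = n, fpairs = fpairs, bf = bf, bgroups = bgroups,
    chol = chol, pinned = pinned,
    inlet_rows = which(bf$bc_type == "inlet"),
    outlet_rows = out_faces,
    wall_rows = which(bf$bc_type == "wall"),
    sym_rows = which(bf$bc_type == "symmetry")
  ), class = "laa_flow_ops")
}

# divergence of face fluxes (1/s); Uf = list(x, y, z), bU per boundary face
flux_divergence <- function(ops, Uf, bU) {
  div <- numeric(ops$n)
  for (ax in c("x", "y", "z")) {
    fp <- ops$fpairs[[ax]]
    if (!length(fp$i)) next
    div[fp$i] <- div[fp$i] + Uf[[ax]]
    div[fp$j] <- div[fp$j] - Uf[[ax]]
  }
  for (g in ops$bgroups) {
    div[ops$bf$cell[g]] <- div[ops$bf$cell[g]] + bU[g]
  }
  div / ops$hm
}

# one projected sub-step; returns updated state
flow_substep <- function(state, ops, props, dt, t_new, inflow, body_force = NULL) {
  n <- ops$n; hm <- ops$hm
  u <- state$u
  nu <- props$nu
  nbr <- ops$grid$nbr
  bf <- ops$bf

  # --- advection (upwind on current face fluxes) and diffusion -------------
  adv <- matrix(0, n, 3)
  diff <- matrix(0, n, 3)
  for (k in 1:3) {
    ax <- c("x", "y", "z")[k]
    fp <- ops$fpairs[[ax]]
    if (length(fp$i)) {
      U <- state$Uf[[ax]]
      up <- ifelse(U > 0, fp$i, fp$j)
      for (comp in 1:3) {
        fl <- U * u[up, comp]
        adv[fp$i, comp] <- adv[fp$i, comp] + fl
        adv[fp$j, comp] <- adv[fp$j, comp] - fl
      }
      # central diffusion across interior faces
      for (comp in 1:3) {
        dd <- (u[fp$j, comp] - u[fp$i, comp])
        diff[fp$i, comp] <- diff[fp$i, comp] + dd
        diff[fp$j, comp] <- diff[fp$j, comp] - dd
      }
    }
  }
  # boundary faces: ghost-cell diffusion and upwind boundary advection
  ub_in <- inflow_velocity_vectors(ops, inflow, t_new)  # inlet face velocity vectors
  for (g in ops$bgroups) {
    cells <- bf$cell[g]
    d <- bf$dir[g[1]]
    nrm <- DIR_VECS[d, ]
    typ <- bf$bc_type[g]
    # wall: ghost = -u  => contribution -2 u
    w <- typ == "wall"
    if (any(w)) diff[cells[w], ] <- diff[cells[w], ] - 2 * u[cells[w], , drop = FALSE]
    # inlet: ghost = 2 u_b - u => contribution 2 (u_b - u)
    i2 <- typ == "inlet"
    if (any(i2)) {
      ubv <- ub_in[match(g[i2], ops$inlet_rows), , drop = FALSE]
      diff[cells[i2], ] <- diff[cells[i2], ] +
        2 * (ubv - u[cells[i2], , drop = FALSE])
      # advective influx carries the inlet velocity vector
      bU <- state$bU[g[i2]]
      for (comp in 1:3) {
        adv[cells[i2], comp] <- adv[cells[i2], comp] + bU * ubv[, comp]
      }
    }
    # outlet: zero-gradient ghost (no diffusive flux); advection carries u
    o <- typ == "outlet"
    if (any(o)) {
      bU <- state$bU[g[o]]
      for (comp in 1:3) {
        adv[cells[o], comp] <- adv[cells[o], comp] + bU * u[cells[o], comp]
      }
    }
    # symmetry: mirror => normal component ghost = -u_n, tangential = u_t
    s <- typ == "symmetry"
    if (any(s)) {
      compn <- DIR_AXIS[d]
      diff[cells[s], compn] <- diff[cells[s], compn] - 2 * u[cells[s], compn]
    }
  }
  adv <- adv / hm
  diff <- diff * (nu / hm^2)

  ustar <- u + dt * (-adv + diff)
  if (!is.null(body_force)) {
    fb <- body_force(t_new)
    ustar <- ustar + dt * matrix(fb, n, 3, byrow = TRUE)
  }

  # --- provisional face fluxes --------------------------------------------
  Uf <- list(x = NULL, y = NULL, z = NULL)
  for (k in 1:3) {
    ax <- c("x", "y", "z")[k]
    fp <- ops$fpairs[[ax]]
    Uf[[ax]] <- if (length(fp$i)) 0.5 * (ustar[fp$i, k] + ustar[fp$j, k]) else numeric(0)
  }
  bU <- numeric(nrow(bf))
  if (length(ops$inlet_rows)) {
    # outward normal velocity at inlet: u_b . n (negative = inflow)
    nrm <- DIR_VECS[bf$dir[ops$inlet_rows], , drop = FALSE]
    bU[ops$inlet_rows] <- rowSums(ub_in * nrm)
  }
  if (length(ops$outlet_rows)) {
    d <- bf$dir[ops$outlet_rows]
    cells <- bf$cell[ops$outlet_rows]
    bU[ops$outlet_rows] <- ustar[cbind(cells, DIR_AXIS[d])] * DIR_SIGN[d]
  }

  # --- pressure projection -------------------------------------------------
  divs <- flux_divergence(ops, Uf, bU)
  p <- as.numeric(Matrix::solve(ops$chol, -divs / dt))

  for (k in 1:3) {
    ax <- c("x", "y", "z")[k]
    fp <- ops$fpairs[[ax]]
    if (length(fp$i)) Uf[[ax]] <- Uf[[ax]] - dt * (p[fp$j] - p[fp$i]) / hm
  }
  if (length(ops$outlet_rows)) {
    cells <- bf$cell[ops$outlet_rows]
    bU[ops$outlet_rows] <- bU[ops$outlet_rows] + 2 * dt * p[cells] / hm
  }

  # cell-centred velocity correction via face-interpolated pressures
  unew <- ustar
  for (k in 1:3) {
    dplus <- c(1L, 3L, 5L)[k]; dminus <- dplus + 1L
    pfp <- p; pfm <- p   # Neumann default: face pressure = cell pressure
    jp <- nbr[, dplus]; jm <- nbr[, dminus]
    hasp <- jp > 0L; hasm <- jm > 0L
    pfp[hasp] <- 0.5 * (p[hasp] + p[jp[hasp]])
    pfm[hasm] <- 0.5 * (p[hasm] + p[jm[hasm]])
    unew[, k] <- ustar[, k] - dt * (pfp - pfm) / hm
  }
  # outlet Dirichlet faces: face pressure 0 (overrides the Neumann default)
  if (length(ops$outlet_rows)) {
    d <- bf$dir[ops$outlet_rows]
    cells <- bf$cell[ops$outlet_rows]
    sgn <- DIR_SIGN[d]
    ax <- DIR_AXIS[d]
    # redo the correction for those cells' outlet-side face
    for (r in seq_along(cells)) {
      k <- ax[r]; cell <- cells[r]
      dplus <- c(1L, 3L, 5L)[k]; dminus <- dplus + 1L
      jp <- nbr[cell, dplus]; jm <- nbr[cell, dminus]
      pfp <- if (sgn[r] > 0) 0 else if (jp > 0L) 0.5 * (p[cell] + p[jp]) else p[cell]
      pfm <- if (sgn[r] < 0) 0 else if (jm > 0L) 0.5 * (p[cell] + p[jm]) else p[cell]
      unew[cell, k] <- ustar[cell, k] - dt * (pfp - pfm) / hm
    }
  }

  maxdiv <- max(abs(flux_divergence(ops, Uf, bU)))
  list(u = unew, Uf = Uf, bU = bU, p = p, t = t_new, max_div = maxdiv)
}

# inlet-face velocity vectors (m/s) at time t: magnitude fn(t) scaled by the
# per-face profile, directed along the per-face inflow direction
inflow_velocity_vectors <- function(ops, inflow, t) {
  rows <- ops$inlet_rows
  if (!length(rows)) return(matrix(0, 0, 3))
  bf <- ops$bf
  mag <- inflow$fn(t) * inflow$profile
  cbind(mag * bf$bdir1[rows], mag * bf$bdir2[rows], mag * bf$bdir3[rows])
}

#' Inflow model from an AF waveform
#'
#' Builds the per-inlet-face inflow profile for an anatomy grid: face
#' velocity = waveform(t) x per-PV scale, directed down the tube axis, with
#' the staircase projection factor so each vein carries waveform x
#' cross-section volume flux.
#'
#' @param grid an `laa_grid` from [discretize_anatomy()]
#' @param waveform an [af_waveform()]
#' @return inflow model for [simulate_flow()]
#' @export
af_inflow <- function(grid, waveform) {
  bf <- grid$bfaces
  rows <- which(bf$bc_type == "inlet")
  pvn <- as.integer(sub("pv_inlet_", "", bf$patch[rows]))
  profile <- bf$scale[rows] * waveform$per_pv_scale[pvn]
  list(fn = function(t) waveform_velocity(waveform, t), profile = profile,
       waveform = waveform)
}

#' Advance the flow one time step
#'
#' Sub-steps automatically when the advective CFL exceeds the cap.
#'
#' @param state flow state (from [flow_init()] or a previous step)
#' @param ops operators from [build_flow_ops()]
#' @param props [fluid_properties()]
#' @param settings [solver_settings()]
#' @param dt step size (s)
#' @param inflow inflow model ([af_inflow()] or compatible), or `NULL`
#' @param body_force `function(t)` returning a length-3 acceleration (m/s^2)
#' @return updated state (fields `u`, `p`, `Uf`, `bU`, `t`, `max_div`)
#' @export
flow_step <- function(state, ops, props, settings, dt, inflow = NULL, body_force = NULL) {
  umax <- max(abs(state$u), if (!is.null(inflow)) abs(inflow$fn(state$t + dt)) else 0, 1e-12)
  cfl <- umax * dt / ops$hm
  nsub <- max(1L, ceiling(cfl / settings$max_cfl))
  # explicit diffusion stability
  dt_diff <- ops$hm^2 / (6 * props$nu)
  nsub <- max(nsub, ceiling(dt / (0.9 * dt_diff)))
  dts <- dt / nsub
  for (s in seq_len(nsub)) {
    state <- flow_substep(state, ops, props, dts, state$t + dts, inflow, body_force)
    if (!all(is.finite(state$u)))
      stop(sprintf("solver error: non-finite velocity at t = %.4f s", state$t))
  }
  state$nsub <- nsub
  state
}

#' Initial (quiescent or prescribed) flow state
#'
#' @param ops operators from [build_flow_ops()]
#' @param u0 optional n x 3 initial velocity (m/s)
#' @param t0 initial time (s)
#' @return a flow state
#' @export
flow_init <- function(ops, u0 = NULL, t0 = 0) {
  n <- ops$n
  u <- if (is.null(u0)) matrix(0, n, 3) else u0
  Uf <- list(x = NULL, y = NULL, z = NULL)
  for (k in 1:3) {
    ax <- c("x", "y", "z")[k]
    fp <- ops$fpairs[[ax]]
    Uf[[ax]] <- if (length(fp$i)) 0.5 * (u[fp$i, k] + u[fp$j, k]) else numeric(0)
  }
  list(u = u, Uf = Uf, bU = numeric(nrow(ops$bf)), p = numeric(n), t = t0,
       max_div = 0)
}

#' Wall shear stress vectors
#'
#' One-sided estimate at every wall and device face: the tangential velocity
#' of the adjacent fluid cell divided by the wall distance (half a cell),
#' times the dynamic viscosity. The face-normal component is removed.
#'
#' @param u n x 3 cell velocities (m/s)
#' @param grid an `laa_grid`
#' @param props [fluid_properties()]
#' @param rows boundary-face rows to evaluate (default: all wall/device faces)
#' @return matrix (length(rows) x 3) of shear vectors (Pa)
#' @export
wall_shear <- function(u, grid, props, rows = NULL) {
  bf <- grid$bfaces
  if (is.null(rows)) rows <- which(bf$bc_type == "wall")
  d <- bf$dir[rows]
  cells <- bf$cell[rows]
  nrm <- DIR_VECS[d, , drop = FALSE]
  uv <- u[cells, , drop = FALSE]
  un <- rowSums(uv * nrm)
  ut <- uv - un * nrm
  hm <- grid$h / 1000
  props$viscosity * ut / (hm / 2)
}

#' Reynolds number
#' @param U mean speed (m/s)
#' @param D hydraulic diameter (m)
#' @param props [fluid_properties()]
#' @return rho U D / mu
#' @export
reynolds_number <- function(U, D, props = fluid_properties()) {
  props$density * U * D / props$viscosity
}

#' Maximum Reynolds number over the tubes and the ostium
#'
#' Hydraulic diameters are the tube diameters (ostium: ostium diameter);
#' mean speeds are volume-flux based for the tubes and the slab average for
#' the ostium.
#'
#' @param state a flow state
#' @param grid an anatomy `laa_grid`
#' @param props [fluid_properties()]
#' @return list: `table` (per region), `max_re`, `laminar` (max Re < 2300)
#' @export
reynolds_check <- function(state, grid, props = fluid_properties()) {
  anatomy <- grid$anatomy
  bf <- grid$bfaces
  res <- list()
  for (i in 1:4) {
    rows <- which(bf$patch == paste0("pv_inlet_", i))
    A <- pi * (anatomy$pv_radius / 1000)^2
    Q <- -sum(state$bU[rows]) * (grid$h / 1000)^2   # influx positive
    U <- abs(Q) / A
    res[[paste0("pv_", i)]] <- reynolds_number(U, 2 * anatomy$pv_radius / 1000, props)
  }
  rows <- which(bf$patch == "mv_outlet")
  A <- pi * (anatomy$mv_radius / 1000)^2
  Q <- sum(state$bU[rows]) * (grid$h / 1000)^2
  res$mv <- reynolds_number(abs(Q) / A, 2 * anatomy$mv_radius / 1000, props)
  # ostium slab: cells within one cell of the ostium plane
  op <- ostium_plane(anatomy)
  ctr <- cell_centers(grid)
  z <- as.vector(sweep(ctr, 2, op$center) %*% op$normal)
  rad <- sqrt(pmax(rowSums(sweep(ctr, 2, op$center)^2) - z^2, 0))
  slab <- abs(z) <= grid$h & rad <= anatomy$laa_ostium_diameter / 2
  U <- if (any(slab)) mean(sqrt(rowSums(state$u[slab, , drop = FALSE]^2))) else 0
  res$ostium <- reynolds_number(U, anatomy$laa_ostium_diameter / 1000, props)
  tab <- unlist(res)
  list(table = tab, max_re = max(tab), laminar = max(tab) < 2300)
}
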