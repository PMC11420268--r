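# Analytic validation benchmarks for the flow and transport solvers.
#
# These exercise the full solver stack against closed-form solutions:
#   * steady plane Poiseuille flow   -> wall shear tau_w = 2 mu u_max / a
#   * oscillatory (Womersley) channel -> truncation-free complex series
#   * single well-mixed compartment  -> washout half-time ln(2) V / Q

#' Analytic oscillatory-channel (Womersley) velocity profile
#'
#' Fully developed flow between parallel plates at `y = +/- a` driven by the
#' pressure gradient `-dp/dx = G cos(omega t)`:
#' `u(y,t) = Re[ G/(i rho omega) (1 - cosh(lambda y)/cosh(lambda a)) e^{i omega t} ]`
#' with `lambda = sqrt(i omega / nu)`.
#'
#' @param y distance from the channel centreline (m), vector
#' @param t time (s), scalar
#' @param a half-gap (m)
#' @param G pressure-gradient amplitude (Pa/m)
#' @param omega angular frequency (1/s)
#' @param props [fluid_properties()]
#' @return velocity (m/s) at each `y`
#' @export
womersley_velocity <- function(y, t, a, G, omega, props = fluid_properties()) {
  lam <- sqrt(complex(real = 0, imaginary = omega / props$nu))
  amp <- G / complex(real = 0, imaginary = props$density * omega)
  Re(amp * (1 - cosh(lam * y) / cosh(lam * a)) * exp(complex(imaginary = omega * t)))
}

#' Plane Poiseuille wall-shear benchmark
#'
#' Simulates a pressure-driven channel (gap `2a` in y, symmetry in z) with a
#' parabolic inlet profile of peak velocity `u_max`, initialized at the exact
#' solution, runs to `t_end`, and compares the measured wall shear at the
#' mid-channel wall faces with the analytic `tau_w = 2 mu u_max / a`.
#'
#' @param u_max peak velocity (m/s)
#' @param a half-gap (m)
#' @param ny cells across the gap (resolution)
#' @param t_end settling time (s)
#' @param dt time step (s)
#' @param props [fluid_properties()]
#' @return list: `tau_measured`, `tau_exact` (Pa), `rel_error`
#' @export
benchmark_poiseuille <- function(u_max = 0.1, a = 0.005, ny = 16,
                                 t_end = 0.3, dt = 0.002,
                                 props = fluid_properties()) {
  h <- 2 * a / ny * 1000             # mm
  nx <- 24L; nz <- 2L
  grid <- make_box_grid(c(nx, ny, nz), h,
                        sides = list(xlo = "inlet", xhi = "outlet",
                                     zlo = "symmetry", zhi = "symmetry"))
  ops <- build_flow_ops(grid)
  ctr <- cell_centers(grid) / 1000   # m
  yc <- ctr[, 2] - a                 # centreline at y = a
  para <- pmax(0, 1 - (yc / a)^2)
  # inlet faces carry the parabolic profile
  rows <- ops$inlet_rows
  prof <- para[grid$bfaces$cell[rows]]
  inflow <- list(fn = function(t) u_max, profile = prof)
  u0 <- cbind(u_max * para, 0, 0)
  st <- solver_settings(dt = dt, warmup_cycles = 0, eval_cycles = 1)
  state <- flow_init(ops, u0)
  nsteps <- round(t_end / dt)
  for (i in seq_len(nsteps)) state <- flow_step(state, ops, props, st, dt, inflow)
  # wall faces in the middle third of the channel length
  bf <- grid$bfaces
  wrows <- which(bf$bc_type == "wall")
  fc <- cell_centers(grid, grid$fluid_idx[bf$cell[wrows]])
  mid <- fc[, 1] > nx * h / 3 & fc[, 1] < 2 * nx * h / 3
  tau <- wall_shear(state$u, grid, props, wrows[mid])
  tau_measured <- mean(sqrt(rowSums(tau^2)))
  tau_exact <- 2 * props$viscosity * u_max / a
  list(tau_measured = tau_measured, tau_exact = tau_exact,
       rel_error = abs(tau_measured - tau_exact) / tau_exact,
       grid = grid, state = state)
}

#' Oscillatory-channel (Womersley) benchmark
#'
#' Body-force-driven oscillatory flow between parallel plates (periodic in
#' x, symmetry in z), initialized at the analytic solution and advanced one
#' full cycle. Reports the relative L2 velocity error over the cycle.
#'
#' @param a half-gap (m)
#' @param G pressure-gradient amplitude (Pa/m)
#' @param period forcing period (s)
#' @param ny cells across the gap
#' @param dt time step (s)
#' @param n_compare number of comparison instants over the cycle
#' @param props [fluid_properties()]
#' @return list: `l2_error` (relative), `alpha` (Womersley number)
#' @export
benchmark_womersley <- function(a = 0.005, G = 200, period = 1.01, ny = 20,
                                dt = 0.0025, n_compare = 10,
                                props = fluid_properties()) {
  omega <- 2 * pi / period
  h <- 2 * a / ny * 1000
  grid <- make_box_grid(c(4L, ny, 1L), h,
                        sides = list(xlo = "periodic", xhi = "periodic",
                                     zlo = "symmetry", zhi = "symmetry"))
  ops <- build_flow_ops(grid)
  ctr <- cell_centers(grid) / 1000
  yc <- ctr[, 2] - a
  u0 <- cbind(womersley_velocity(yc, 0, a, G, omega, props), 0, 0)
  st <- solver_settings(dt = dt, warmup_cycles = 0, eval_cycles = 1)
  state <- flow_init(ops, u0)
  force <- function(t) c(G / props$density * cos(omega * t), 0, 0)
  nsteps <- round(period / dt)
  check_every <- max(1L, round(nsteps / n_compare))
  num2 <- 0; den2 <- 0
  for (i in seq_len(nsteps)) {
    state <- flow_step(state, ops, props, st, dt, inflow = NULL, body_force = force)
    if (i %% check_every == 0L) {
      ue <- womersley_velocity(yc, state$t, a, G, omega, props)
      num2 <- num2 + sum((state$u[, 1] - ue)^2)
      den2 <- den2 + sum(ue^2)
    }
  }
  list(l2_error = sqrt(num2 / den2), alpha = a * sqrt(omega / props$nu),
       grid = grid, state = state)
}

#' Well-mixed-compartment washout benchmark
#'
#' A box one cell deep in the flow direction behaves as a continuously
#' stirred compartment: with volume `V` and throughflow `Q` the residual
#' fraction decays as `exp(-Q t / V)`, so the half-time is `ln(2) V / Q`.
#' The flow is produced by the solver (uniform plug flow between an inlet
#' and an outlet, symmetry on the lateral sides), the tracer by
#' [advect_tracer()], and the half-time by [washout_halftime()].
#'
#' @param u0 plug-flow speed (m/s)
#' @param h cell size (mm)
#' @param n_cross lateral cells (the cross-section is `n_cross` squared)
#' @param dt tracer/flow step (s)
#' @return list: `t_half`, `t_half_exact` (s), `rel_error`, `phi` curve
#' @export
benchmark_washout <- function(u0 = 0.05, h = 5, n_cross = 3, dt = 0.002) {
  props <- fluid_properties()
  grid <- make_box_grid(c(1L, n_cross, n_cross), h,
                        sides = list(xlo = "inlet", xhi = "outlet",
                                     ylo = "symmetry", yhi = "symmetry",
                                     zlo = "symmetry", zhi = "symmetry"))
  ops <- build_flow_ops(grid)
  st <- solver_settings(dt = dt, warmup_cycles = 0, eval_cycles = 1)
  inflow <- list(fn = function(t) u0, profile = rep(1, length(ops$inlet_rows)))
  state <- flow_init(ops, cbind(rep(u0, ops$n), 0, 0))
  for (i in 1:5) state <- flow_step(state, ops, props, st, dt, inflow)
  hm <- grid$h / 1000
  t_half_exact <- log(2) * hm / u0          # V/Q = h/u for a one-cell column
  conc <- rep(1, ops$n)
  nsteps <- ceiling(4 * t_half_exact / dt)
  phi <- numeric(nsteps); tt <- numeric(nsteps)
  for (i in seq_len(nsteps)) {
    conc <- advect_tracer(conc, ops, state$Uf, state$bU, dt)
    phi[i] <- residual_fraction(conc, rep(TRUE, ops$n), grid$cell_volume)
    tt[i] <- i * dt
  }
  wh <- washout_halftime(c(0, tt), c(1, phi))
  list(t_half = wh$t_half, t_half_exact = t_half_exact,
       rel_error = abs(wh$t_half - t_half_exact) / t_half_exact,
       times = tt, phi = phi)
}
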