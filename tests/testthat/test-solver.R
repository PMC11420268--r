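# Flow solver: null solutions, analytic channel benchmarks, conservation,
# no-slip and determinism.

test_that("zero inflow and zero initial field stay identically zero", {
  g <- make_box_grid(c(4, 4, 4), 2)
  ops <- build_flow_ops(g)
  st <- solver_settings(dt = 0.005)
  props <- fluid_properties()
  state <- flow_init(ops)
  for (i in 1:5) state <- flow_step(state, ops, props, st, 0.005)
  expect_equal(max(abs(state$u)), 0)
  expect_equal(max(abs(state$p)), 0)
})

test_that("plane Poiseuille wall shear is within 5% of 2 mu u_max / a", {
  b <- benchmark_poiseuille(u_max = 0.1, a = 0.005, ny = 16)
  expect_equal(b$tau_exact, 0.14, tolerance = 1e-12)
  expect_lt(b$rel_error, 0.05)
})

test_that("Poiseuille wall-shear error decreases under refinement", {
  e_coarse <- benchmark_poiseuille(ny = 8, t_end = 0.2)$rel_error
  e_fine <- benchmark_poiseuille(ny = 16, t_end = 0.2)$rel_error
  expect_lt(e_fine, e_coarse)
})

test_that("oscillatory channel flow matches the Womersley series within 5%", {
  b <- benchmark_womersley()
  expect_lt(b$l2_error, 0.05)
  expect_gt(b$alpha, 1)   # genuinely pulsatile regime
})

test_that("wall shear of imposed linear shear is exact; quiescent fluid zero", {
  g <- make_box_grid(c(4, 6, 4), 1)
  props <- fluid_properties()
  ctr <- cell_centers(g) / 1000
  gamma <- 50  # 1/s
  u <- cbind(gamma * ctr[, 2], 0, 0)
  rows <- which(g$bfaces$bc_type == "wall" & g$bfaces$dir == 4)  # y = 0 wall
  tau <- wall_shear(u, g, props, rows)
  # one-sided gradient at the first cell centre: u(h/2)/(h/2) = gamma exactly
  expect_equal(unname(tau[, 1]), rep(props$viscosity * gamma, length(rows)),
               tolerance = 1e-12)
  expect_equal(unname(tau[, 2]), rep(0, length(rows)))
  tau0 <- wall_shear(matrix(0, g$n_fluid, 3), g, props)
  expect_equal(max(abs(tau0)), 0)
})

test_that("global mass balance holds every step of a pulsatile run", {
  g <- default_grid()
  ops <- build_flow_ops(g)
  props <- fluid_properties()
  st <- solver_settings(dt = 0.005)
  inflow <- af_inflow(g, af_waveform())
  state <- flow_init(ops)
  worst <- 0
  for (i in 1:20) {
    state <- flow_step(state, ops, props, st, 0.005, inflow)
    worst <- max(worst, laaoflow:::mass_balance_residual(ops, state))
  }
  expect_lt(worst, 10 * st$convergence_tol)
})

test_that("reynolds number arithmetic and laminar flag", {
  props <- fluid_properties()
  expect_equal(reynolds_number(0.5, 0.010, props), 1060 * 0.5 * 0.01 / 0.0035,
               tolerance = 1e-12)
  expect_equal(round(reynolds_number(0.5, 0.010, props)), 1514)
  expect_equal(reynolds_number(0, 0.010, props), 0)
  # parabolic tube profile: cross-section (disc) mean = u_max / 2, Re matches
  u_max <- 0.4; R <- 0.005
  xy <- seq(-R + R / 60, R, by = R / 30)
  gridpts <- expand.grid(x = xy, y = xy)
  r2 <- gridpts$x^2 + gridpts$y^2
  prof <- u_max * (1 - r2 / R^2)
  U <- mean(prof[r2 <= R^2])
  expect_equal(U, u_max / 2, tolerance = 0.01)
  expect_equal(reynolds_number(U, 2 * R, props),
               props$density * u_max / 2 * 2 * R / props$viscosity,
               tolerance = 0.01)
})

test_that("kinetic energy stays bounded over repeated forced cycles", {
  b <- benchmark_womersley(ny = 10, dt = 0.005, n_compare = 2)
  ke <- sum(b$state$u^2)
  expect_true(is.finite(ke))
  expect_lt(max(abs(b$state$u)), 1)   # m/s, far below divergence
})

test_that("two identical runs produce bit-identical fields", {
  run_once <- function() {
    g <- make_box_grid(c(4, 4, 2), 2, sides = list(xlo = "inlet", xhi = "outlet"))
    ops <- build_flow_ops(g)
    st <- solver_settings(dt = 0.004)
    inflow <- list(fn = function(t) 0.05 * (1 + sin(2 * pi * t)),
                   profile = rep(1, sum(g$bfaces$bc_type == "inlet")))
    state <- flow_init(ops)
    props <- fluid_properties()
    for (i in 1:25) state <- flow_step(state, ops, props, st, 0.004, inflow)
    state$u
  }
  expect_identical(run_once(), run_once())
})

test_that("paper-protocol step counts follow from the settings arithmetic", {
  st <- solver_settings(dt = 0.005, warmup_cycles = 10, eval_cycles = 6)
  period <- af_waveform()$period
  expect_equal(round(st$warmup_cycles * period / st$dt), 2020)
  expect_equal(round(st$eval_cycles * period / st$dt), 1212)
})

test_that("AF waveform is periodic, non-negative, and has no A wave", {
  w <- af_waveform()
  t <- seq(0, 3 * w$period, by = 0.001)
  v <- waveform_velocity(w, t)
  expect_true(all(v >= 0))
  expect_equal(waveform_velocity(w, t), waveform_velocity(w, t + w$period),
               tolerance = 1e-12)
  # exactly two local maxima per cycle (S and D waves, no A wave)
  one <- waveform_velocity(w, seq(0, w$period, length.out = 2000))
  peaks <- sum(diff(sign(diff(one))) == -2)
  expect_equal(peaks, 2)
})
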