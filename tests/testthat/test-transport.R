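# Tracer transport: conservation, monotonicity, translation oracle,
# residual fraction and washout half-time.

test_that("uniform tracer with zero flow is unchanged", {
  g <- make_box_grid(c(5, 4, 3), 2)
  ops <- build_flow_ops(g)
  state <- flow_init(ops)
  conc <- rep(1, ops$n)
  conc2 <- advect_tracer(conc, ops, state$Uf, state$bU, 0.01)
  expect_identical(conc2, conc)
})

test_that("1d step translation conserves mass and stays monotone", {
  # uniform plug flow through a channel; step profile advected k cells
  sb <- steady_box_flow(n = c(24, 3, 3), h = 2, u0 = 0.05)
  ops <- sb$ops
  ctr <- cell_centers(sb$grid)
  conc <- as.numeric(ctr[, 1] < 12)   # step across x = 12 mm
  h_m <- sb$grid$h / 1000
  k <- 6L
  t_total <- k * h_m / sb$u0
  nsteps <- 60L
  dt <- t_total / nsteps
  for (i in seq_len(nsteps)) {
    conc <- advect_tracer(conc, ops, sb$state$Uf, sb$state$bU, dt, inlet_c = 1)
  }
  # no new extrema
  expect_gte(min(conc), 0 - 1e-12)
  expect_lte(max(conc), 1 + 1e-12)
  # the step's midpoint has moved by k cells (centre of mass of 1 - c)
  front <- sum((1 - conc[seq_len(24)]))  # cells above the front in one column
  expect_equal(24 - front, 12 / 2 + k, tolerance = 1)
  # conservation: with inlet_c = 1 and outflow c = 1 far behind the front,
  # total mass change equals net boundary flux; verify directly on a closed box
  g2 <- make_box_grid(c(6, 6, 3), 2)
  ops2 <- build_flow_ops(g2)
  ctr2 <- cell_centers(g2) / 1000
  u0 <- cbind(-(ctr2[, 2] - 0.006), ctr2[, 1] - 0.006, 0)
  st2 <- flow_init(ops2, u0)
  props <- fluid_properties()
  st2 <- flow_step(st2, ops2, props, solver_settings(dt = 0.004), 0.004)
  c2 <- 0.5 + 0.4 * sin(ctr2[, 1] * 700) * cos(ctr2[, 2] * 600)
  tot <- sum(c2)
  for (i in 1:40) c2 <- advect_tracer(c2, ops2, st2$Uf, st2$bU, 0.004)
  expect_equal(sum(c2), tot, tolerance = 1e-12)
})

test_that("translation error at least halves under 2x refinement", {
  err_at <- function(nx) {
    sb <- steady_box_flow(n = c(nx, 3, 3), h = 48 / nx, u0 = 0.05, nsteps = 6)
    ctr <- cell_centers(sb$grid)
    x <- ctr[, 1]
    bump <- function(x) ifelse(abs(x - 12) < 8, cos(pi * (x - 12) / 16)^2, 0)
    conc <- bump(x)
    h_m <- sb$grid$h / 1000
    t_total <- 10 * (48 / 24) * 1e-3 / sb$u0   # shift by 20 mm
    nsteps <- 200L
    dt <- t_total / nsteps
    for (i in seq_len(nsteps)) {
      conc <- advect_tracer(conc, sb$ops, sb$state$Uf, sb$state$bU, dt)
    }
    exact <- bump(x - 20)
    cols <- x > 0  # all cells; profile uniform in y, z
    sqrt(mean((conc[cols] - exact[cols])^2))
  }
  e1 <- err_at(24)
  e2 <- err_at(48)
  expect_lt(e2, e1 / 2)
})

test_that("residual fraction reproduces hand-computed values", {
  mask <- c(TRUE, TRUE, TRUE, FALSE)
  expect_equal(residual_fraction(rep(1, 4), mask), 1)
  expect_equal(residual_fraction(rep(0.5, 4), mask), 0.5)
  # brute force on a random toy field with unequal masks
  set.seed(42)
  cc <- runif(20)
  m <- runif(20) > 0.4
  expect_equal(residual_fraction(cc, m, 2.5),
               sum(cc[m] * 2.5) / (sum(m) * 2.5))
  # binary-threshold variant
  expect_equal(residual_fraction(cc, m, 1, threshold = 0.5),
               mean(cc[m] >= 0.5))
  expect_error(residual_fraction(cc, rep(FALSE, 20)), "empty")
})

test_that("washout half-time: closed form, censoring and multi-crossing", {
  # single well-mixed compartment, V = 10 mL, Q = 5 mL/s
  V <- 10; Q <- 5
  t <- seq(0, 4, by = 0.01)
  phi <- exp(-Q * t / V)
  w <- washout_halftime(t, phi)
  expect_false(w$censored)
  expect_equal(w$t_half, log(2) * V / Q, tolerance = 1e-4)
  # sealed dead end: constant 1 -> censored
  wc <- washout_halftime(t, rep(1, length(t)))
  expect_true(wc$censored)
  expect_true(is.na(wc$t_half))
  # non-monotone curve re-crossing 0.5: first crossing kept, flagged
  phi2 <- c(1, 0.8, 0.45, 0.6, 0.4, 0.3)
  w2 <- washout_halftime(0:5, phi2)
  expect_true(w2$multi_crossing)
  expect_equal(w2$t_half, 1 + (0.8 - 0.5) / (0.8 - 0.45), tolerance = 1e-12)
})

test_that("well-mixed compartment half-time is recovered within 2%", {
  b <- benchmark_washout()
  expect_lt(b$rel_error, 0.02)
})

test_that("two-compartment cascade matches the ODE oracle within 2%", {
  # two cells in series behave as two equal stirred tanks: the closed-form
  # solution of the ODE cascade is c1 = e^{-kt}, c2 = (1 + kt) e^{-kt}
  u0 <- 0.05; h <- 5
  g <- make_box_grid(c(2L, 3L, 3L), h,
                     sides = list(xlo = "inlet", xhi = "outlet",
                                  ylo = "symmetry", yhi = "symmetry",
                                  zlo = "symmetry", zhi = "symmetry"))
  ops <- build_flow_ops(g)
  st <- solver_settings(dt = 0.002)
  inflow <- list(fn = function(t) u0, profile = rep(1, length(ops$inlet_rows)))
  props <- fluid_properties()
  state <- flow_init(ops, cbind(rep(u0, ops$n), 0, 0))
  for (i in 1:5) state <- flow_step(state, ops, props, st, 0.002, inflow)
  kk <- u0 / (h / 1000)
  conc <- rep(1, ops$n)
  dt <- 5e-4
  t_end <- 0.25
  nst <- round(t_end / dt)
  phi <- numeric(nst)
  for (i in seq_len(nst)) {
    conc <- advect_tracer(conc, ops, state$Uf, state$bU, dt)
    phi[i] <- mean(conc)
  }
  tt <- dt * seq_len(nst)
  phi_exact <- (exp(-kk * tt) + (1 + kk * tt) * exp(-kk * tt)) / 2
  expect_lt(max(abs(phi - phi_exact) / pmax(phi_exact, 0.05)), 0.02)
})

test_that("faster throughflow shortens the half-time (monotonicity)", {
  t1 <- benchmark_washout(u0 = 0.03)$t_half
  t2 <- benchmark_washout(u0 = 0.06)$t_half
  t3 <- benchmark_washout(u0 = 0.12)$t_half
  expect_gt(t1, t2)
  expect_gt(t2, t3)
})
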