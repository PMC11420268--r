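# Shared fixtures, built once per test run.
#
# The default anatomy discretized at the coarse study resolution is used by
# several test files; memoise it so the suite stays fast.

fixture_env <- new.env(parent = emptyenv())

default_anatomy <- function() {
  if (is.null(fixture_env$anatomy)) fixture_env$anatomy <- laa_anatomy()
  fixture_env$anatomy
}

default_grid <- function(h = 2.5) {
  key <- paste0("grid_", h)
  if (is.null(fixture_env[[key]]))
    fixture_env[[key]] <- discretize_anatomy(default_anatomy(), h)
  fixture_env[[key]]
}

# a small steady flow state in a box, for transport tests
steady_box_flow <- function(n = c(6, 4, 4), h = 2, u0 = 0.05, nsteps = 10) {
  grid <- make_box_grid(n, h, sides = list(xlo = "inlet", xhi = "outlet",
                                           ylo = "symmetry", yhi = "symmetry",
                                           zlo = "symmetry", zhi = "symmetry"))
  ops <- build_flow_ops(grid)
  st <- solver_settings(dt = 0.002)
  inflow <- list(fn = function(t) u0, profile = rep(1, sum(grid$bfaces$bc_type == "inlet")))
  state <- flow_init(ops, cbind(rep(u0, ops$n), 0, 0))
  props <- fluid_properties()
  for (i in seq_len(nsteps)) state <- flow_step(state, ops, props, st, 0.002, inflow)
  list(grid = grid, ops = ops, state = state, props = props, u0 = u0)
}
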