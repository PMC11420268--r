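# Scenario configuration and end-to-end orchestration:
# anatomy -> implantation -> flow -> tracer washout -> markers -> report.

#' Scenario configuration
#'
#' A full declarative description of one simulated case. `device` and
#' `placement` are `NULL` for the pre-occlusion model.
#'
#' @param name scenario label (e.g. `"np_os"`)
#' @param anatomy an [laa_anatomy()]
#' @param device an [laao_device()] or `NULL`
#' @param placement an [laa_placement()] or `NULL`
#' @param fluid [fluid_properties()]
#' @param waveform [af_waveform()]
#' @param roi_diameter ROI sphere diameter (mm)
#' @return object of class `laa_scenario`
#' @export
laa_scenario <- function(name, anatomy = laa_anatomy(), device = NULL,
                         placement = NULL, fluid = fluid_properties(),
                         waveform = af_waveform(), roi_diameter = 40) {
  if (!is.null(device) && is.null(placement))
    stop("a device requires a placement")
  structure(list(name = name, anatomy = anatomy, device = device,
                 placement = placement, fluid = fluid, waveform = waveform,
                 roi_diameter = roi_diameter), class = "laa_scenario")
}

#' @export
print.laa_scenario <- function(x, ...) {
  cat("laa_scenario:", x$name, "\n")
  if (is.null(x$device)) cat("  pre-occlusion (no device)\n")
  else cat("  device:", x$device$family, x$device$nominal_size,
           "| depth offset", x$placement$depth_offset, "mm, tilt",
           x$placement$tilt, "deg\n")
  invisible(x)
}

#' Resolution tiers
#'
#' `test` is the scaled-down regime used throughout the test-suite runs
#' (coarse grid, 2 warm-up + 2 evaluation cycles); `standard` and `fine`
#' increase resolution and cycle counts toward the full protocol of 10
#' warm-up + 6 evaluation cycles.
#'
#' @param tier `"test"`, `"standard"` or `"fine"`
#' @return list: `h` (mm), [solver_settings()]
#' @export
tier_settings <- function(tier = c("test", "standard", "fine")) {
  tier <- match.arg(tier)
  switch(tier,
    test = list(h = 2.5, settings = solver_settings(dt = 0.005, warmup_cycles = 2,
                                                    eval_cycles = 2, save_stride = 2)),
    standard = list(h = 2.0, settings = solver_settings(dt = 0.005, warmup_cycles = 4,
                                                        eval_cycles = 4, save_stride = 2)),
    fine = list(h = 1.6, settings = solver_settings(dt = 0.005, warmup_cycles = 10,
                                                    eval_cycles = 6, save_stride = 2))
  )
}

#' The nine-scenario study suite
#'
#' Pre-occlusion plus eight implanted configurations: the plug (non-pacifier,
#' NP) occluder in clinically-implanted (slightly proximal), ostium-fitted,
#' tilted and deep positions, and the large (LP) and small (SP) disc
#' (pacifier) occluders in ostial and deep positions. Deep placements target
#' the study's LUPV ridge lengths (NP 27 mm, SP 15.5 mm, LP 10.1 mm); deep
#' plug implantation uses the smaller plug (size 24), mirroring the rule
#' that the deep position is only achievable with a smaller device.
#'
#' @param anatomy an [laa_anatomy()]
#' @param waveform an [af_waveform()]
#' @param fluid [fluid_properties()]
#' @return named list of nine [laa_scenario()] objects
#' @export
scenario_suite <- function(anatomy = laa_anatomy(), waveform = af_waveform(),
                           fluid = fluid_properties()) {
  w27 <- laao_device("non_pacifier", 27)
  w24 <- laao_device("non_pacifier", 24)
  a25 <- laao_device("pacifier", 25)
  a22 <- laao_device("pacifier", 22)
  disc_os <- function(dev) laa_placement(depth_offset = -dev$disc_thickness)
  sc <- function(name, device = NULL, placement = NULL)
    laa_scenario(name, anatomy, device, placement, fluid, waveform)
  list(
    pre_laao = sc("pre_laao"),
    np_cl = sc("np_cl", w27, laa_placement(depth_offset = -3)),
    np_os = sc("np_os", w27, laa_placement(depth_offset = 0)),
    np_tl = sc("np_tl", w27, laa_placement(depth_offset = 2, tilt = -13.6,
                                           tilt_toward = "lupv",
                                           lateral_offset = 4,
                                           lateral_toward = "mv")),
    np_ds = sc("np_ds", w24, laa_placement(depth_offset = depth_for_ridge(anatomy, 27))),
    lp_os = sc("lp_os", a25, disc_os(a25)),
    lp_ds = sc("lp_ds", a25, laa_placement(depth_offset = depth_for_ridge(anatomy, 10.1))),
    sp_os = sc("sp_os", a22, disc_os(a22)),
    sp_ds = sc("sp_ds", a22, laa_placement(depth_offset = depth_for_ridge(anatomy, 15.5)))
  )
}

#' Run one scenario end to end
#'
#' Builds the grid, deploys the device, runs warm-up then evaluation cycles
#' with the old-blood tracer, and computes all markers. Deterministic: two
#' runs with the same configuration produce identical results.
#'
#' @param scenario an [laa_scenario()]
#' @param tier resolution tier (see [tier_settings()])
#' @param verbose print stage progress
#' @return object of class `laa_run`: the marker report row plus stored
#'   curves, fields and diagnostics
#' @export
run_scenario <- function(scenario, tier = "test", verbose = FALSE) {
  ts <- tier_settings(tier)
  st <- ts$settings
  say <- function(...) if (verbose) message(sprintf(...))
  t_start <- Sys.time()

  say("[%s] building anatomy grid (h = %.2f mm)", scenario$name, ts$h)
  grid <- discretize_anatomy(scenario$anatomy, ts$h)

  position <- NULL
  release_warning <- NA_character_
  sealed <- NA
  if (!is.null(scenario$device)) {
    say("[%s] deploying %s %s", scenario$name, scenario$device$family,
        scenario$device$nominal_size)
    dep <- withCallingHandlers(
      deploy(grid, scenario$device, scenario$placement),
      laaoflow_release_warning = function(w) {
        release_warning <<- conditionMessage(w)
        invokeRestart("muffleWarning")
      })
    grid <- dep$grid
    sealed <- dep$sealed
    position <- measure_position(scenario$anatomy, scenario$device,
                                 scenario$placement, dep$compression_rate)
  }

  roi <- build_roi(grid, scenario$device, scenario$placement,
                   diameter = scenario$roi_diameter)
  ops <- build_flow_ops(grid)
  inflow <- af_inflow(grid, scenario$waveform)
  props <- scenario$fluid
  Tc <- scenario$waveform$period
  dt <- st$dt
  n_warm <- round(st$warmup_cycles * Tc / dt)
  n_eval <- round(st$eval_cycles * Tc / dt)

  say("[%s] warm-up: %d steps", scenario$name, n_warm)
  state <- flow_init(ops)
  for (i in seq_len(n_warm)) state <- flow_step(state, ops, props, st, dt, inflow)

  say("[%s] evaluation: %d steps with tracer", scenario$name, n_eval)
  tau_rows <- roi_surface_faces(grid, roi)
  areas <- grid$bfaces$area[tau_rows]
  conc <- rep(1, ops$n)
  t0 <- state$t
  nsave <- floor(n_eval / st$save_stride)
  u_series <- vector("list", nsave)
  tau_series <- array(0, c(nsave, length(tau_rows), 3))
  t_save <- numeric(nsave)
  phi_t <- numeric(n_eval); phi_dom <- numeric(n_eval); t_phi <- numeric(n_eval)
  mass_resid <- numeric(n_eval)
  isave <- 0L
  for (i in seq_len(n_eval)) {
    state <- flow_step(state, ops, props, st, dt, inflow)
    conc <- advect_tracer(conc, ops, state$Uf, state$bU, dt)
    phi_t[i] <- residual_fraction(conc, roi$mask, grid$cell_volume)
    phi_dom[i] <- mean(conc)
    t_phi[i] <- state$t - t0
    mass_resid[i] <- mass_balance_residual(ops, state)
    if (i %% st$save_stride == 0L) {
      isave <- isave + 1L
      u_series[[isave]] <- state$u
      tau_series[isave, , ] <- wall_shear(state$u, grid, props, tau_rows)
      t_save[isave] <- state$t - t0
    }
  }

  # markers over the last stored cycle
  last <- t_save > (st$eval_cycles - 1) * Tc - 1e-9
  stats <- roi_flow_stats(u_series[last], t_save[last], grid, roi$mask)
  tw <- tawss(tau_series[last, , , drop = FALSE], t_save[last])
  os <- osi(tau_series[last, , , drop = FALSE], t_save[last])
  wash <- washout_halftime(t_phi, phi_t)
  report <- build_report(scenario$name, stats, wash, phi_t[n_eval],
                         tw, os, areas, position)
  re <- reynolds_check(state, grid, props)

  # cycle-to-cycle periodicity: drift of the cycle-mean ROI speed
  drift <- NA_real_
  if (st$eval_cycles >= 2) {
    cyc <- findInterval(t_save - 1e-9, seq(0, st$eval_cycles * Tc, by = Tc))
    sp <- vapply(u_series, function(u) mean(sqrt(rowSums(u[roi$mask, , drop = FALSE]^2))),
                 numeric(1))
    ms <- tapply(sp, cyc, mean)
    drift <- abs(ms[length(ms)] - ms[length(ms) - 1]) / max(ms[length(ms)], 1e-12)
  }

  structure(list(
    scenario = scenario, tier = tier, grid = grid, roi = roi,
    position = position, sealed = sealed, release_warning = release_warning,
    report = report,
    curves = list(t = t_phi, phi_roi = phi_t, phi_domain = phi_dom),
    t_save = t_save, u_series = u_series, tau_series = tau_series,
    tau_rows = tau_rows, face_areas = areas, conc_final = conc,
    diagnostics = list(mass_residual_max = max(mass_resid),
                       max_div = state$max_div, periodicity_drift = drift,
                       reynolds = re,
                       runtime_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))),
    settings = st, h = ts$h
  ), class = "laa_run")
}

# relative global mass imbalance |influx - outflux| / influx for a state
mass_balance_residual <- function(ops, state) {
  bf <- ops$bf
  infl <- -sum(state$bU[ops$inlet_rows])
  outfl <- sum(state$bU[ops$outlet_rows])
  if (abs(infl) < 1e-14) return(abs(outfl))
  abs(infl - outfl) / abs(infl)
}

#' @export
print.laa_run <- function(x, ...) {
  cat("laa_run:", x$scenario$name, "(tier", x$tier, ")\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Run a set of scenarios and assemble the comparative report
#'
#' Scenarios are run independently; a failing scenario is reported and the
#' others continue. With `out_dir` set, the report (CSV + JSON), the phi(t)
#' curves and a run manifest are written there.
#'
#' @param scenarios named list of [laa_scenario()] (default: the built-in
#'   nine-scenario suite)
#' @param tier resolution tier
#' @param out_dir optional output directory
#' @param verbose print stage progress
#' @return object of class `laa_study`: list(report, runs, failures)
#' @export
run_study <- function(scenarios = scenario_suite(), tier = "test",
                      out_dir = NULL, verbose = FALSE) {
  runs <- list(); failures <- list()
  for (nm in names(scenarios)) {
    res <- tryCatch(run_scenario(scenarios[[nm]], tier, verbose),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[[nm]] <- conditionMessage(res)
      warning("scenario ", nm, " failed: ", conditionMessage(res))
    } else runs[[nm]] <- res
  }
  report <- do.call(rbind, lapply(runs, function(r) r$report))
  rownames(report) <- NULL
  study <- structure(list(report = report, runs = runs, failures = failures,
                          tier = tier), class = "laa_study")
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

#' @export
print.laa_study <- function(x, ...) {
  cat("laa_study (tier ", x$tier, "): ", nrow(x$report), " scenarios\n", sep = "")
  print(x$report[, c("scenario", "avg_velocity", "washout_half_time", "phi_final",
                     "avg_wss", "avg_ecap", "frac_area_high_ecap")], row.names = FALSE)
  if (length(x$failures)) cat("failures:", paste(names(x$failures), collapse = ", "), "\n")
  invisible(x)
}

#' Pairwise position/device contrasts
#'
#' Signed differences of each marker for the comparisons of interest:
#' deep vs ostial (per device), tilted vs ostial (plug), and disc vs plug
#' at the ostial position.
#'
#' @param report the `report` data.frame of an `laa_study`
#' @return data.frame of contrasts with direction labels
#' @export
compare_scenarios <- function(report) {
  if (nrow(report) < 2) stop("need at least two scenarios to compare")
  markers <- c("phi_final", "avg_wss", "avg_ecap", "avg_velocity",
               "washout_half_time", "frac_area_high_ecap")
  pairs <- list(
    c("np_ds", "np_os"), c("np_tl", "np_os"),
    c("sp_ds", "sp_os"), c("lp_ds", "lp_os"),
    c("lp_os", "np_os"), c("sp_os", "np_os")
  )
  out <- list()
  for (p in pairs) {
    if (!all(p %in% report$scenario)) next
    a <- report[report$scenario == p[1], ]
    b <- report[report$scenario == p[2], ]
    for (m in markers) {
      d <- a[[m]] - b[[m]]
      out[[length(out) + 1]] <- data.frame(
        comparison = paste(p[1], "vs", p[2]), marker = m,
        value_a = a[[m]], value_b = b[[m]], difference = d,
        direction = if (is.na(d)) "undefined" else if (d > 0) "higher" else if (d < 0) "lower" else "equal",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
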