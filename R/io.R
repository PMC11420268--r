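# Output writers: study reports (CSV/JSON), phi(t) curves, legacy-VTK field
# snapshots for external visualization, YAML scenario configs, manifest.

#' Write a study's report, curves and manifest
#'
#' @param study an `laa_study` from [run_study()]
#' @param out_dir output directory (created if missing)
#' @return `out_dir`, invisibly
#' @export
write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$report, file.path(out_dir, "report.csv"), row.names = FALSE)
  jsonlite::write_json(study$report, file.path(out_dir, "report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null")
  curves <- do.call(rbind, lapply(names(study$runs), function(nm) {
    cv <- study$runs[[nm]]$curves
    data.frame(scenario = nm, t = cv$t, phi_roi = cv$phi_roi,
               phi_domain = cv$phi_domain)
  }))
  if (!is.null(curves))
    utils::write.csv(curves, file.path(out_dir, "washout_curves.csv"), row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("laaoflow")),
    tier = study$tier,
    scenarios = names(study$runs),
    failures = study$failures,
    diagnostics = lapply(study$runs, function(r)
      r$diagnostics[c("mass_residual_max", "max_div", "periodicity_drift", "runtime_s")]),
    report_hash = report_hash(study$report),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

# deterministic content hash of a report table (platform-stable text digest)
report_hash <- function(report) {
  txt <- paste(utils::capture.output(utils::write.csv(format(report, digits = 15),
                                                      row.names = FALSE)),
               collapse = "\n")
  # simple stable polynomial digest (exact in double arithmetic)
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write cell fields as a legacy-VTK structured-points file
#'
#' ASCII, readable by standard visualization tools. Fluid-cell fields are
#' scattered into the full voxel block; non-fluid cells carry 0 and a
#' `cell_class` array distinguishes solid/fluid/device.
#'
#' @param grid an `laa_grid`
#' @param fields named list of per-fluid-cell vectors (scalars) or n x 3
#'   matrices (vectors)
#' @param path output `.vtk` file
#' @return `path`, invisibly
#' @export
write_vtk <- function(grid, fields, path) {
  d <- grid$dims
  ntot <- prod(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "laaoflow field snapshot", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               sprintf("ORIGIN %g %g %g", grid$origin[1] + grid$h / 2,
                       grid$origin[2] + grid$h / 2, grid$origin[3] + grid$h / 2),
               sprintf("SPACING %g %g %g", grid$h, grid$h, grid$h),
               sprintf("POINT_DATA %d", ntot)), con)
  writeLines(c("SCALARS cell_class int 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(as.vector(grid$cell_class)), con)
  for (nm in names(fields)) {
    f <- fields[[nm]]
    if (is.matrix(f) && ncol(f) == 3) {
      full <- matrix(0, ntot, 3)
      full[grid$fluid_idx, ] <- f
      writeLines(sprintf("VECTORS %s float", nm), con)
      writeLines(sprintf("%g %g %g", full[, 1], full[, 2], full[, 3]), con)
    } else {
      full <- numeric(ntot)
      full[grid$fluid_idx] <- f
      writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%g", full), con)
    }
  }
  invisible(path)
}

#' Serialize a scenario configuration to YAML
#'
#' Round-trip stable with [scenario_from_config()].
#'
#' @param scenario an [laa_scenario()]
#' @param path optional file; otherwise the YAML text is returned
#' @return the YAML string, invisibly if written to file
#' @export
scenario_to_config <- function(scenario, path = NULL) {
  a <- scenario$anatomy
  cfg <- list(
    name = scenario$name,
    anatomy = list(
      chamber_radii = as.numeric(a$chamber_radii),
      pv_dirs = lapply(seq_len(4), function(i) as.numeric(a$pv_dirs[i, ])),
      pv_radius = a$pv_radius, pv_length = a$pv_length,
      mv_dir = as.numeric(a$mv_dir), mv_radius = a$mv_radius,
      mv_length = a$mv_length, laa_dir = as.numeric(a$laa_dir),
      laa_ostium_diameter = a$laa_ostium_diameter, laa_depth = a$laa_depth,
      laa_taper = a$laa_taper, wall_resolution = a$wall_resolution),
    device = if (is.null(scenario$device)) NULL else {
      d <- scenario$device
      list(family = d$family, nominal_size = d$nominal_size,
           deployed_diameter = d$deployed_diameter,
           body_length = d$body_length, disc_thickness = d$disc_thickness,
           cove_radius = d$cove_radius, cove_depth = d$cove_depth,
           shoulder_radius = d$shoulder_radius,
           insert_radius = d$insert_radius, insert_height = d$insert_height)
    },
    placement = if (is.null(scenario$placement)) NULL else unclass(scenario$placement),
    fluid = list(density = scenario$fluid$density,
                 viscosity = scenario$fluid$viscosity),
    waveform = unclass(scenario$waveform),
    roi_diameter = scenario$roi_diameter
  )
  txt <- yaml::as.yaml(cfg, precision = 15)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

#' Rebuild a scenario from a YAML configuration
#'
#' @param x YAML text or a file path
#' @return an [laa_scenario()]
#' @export
scenario_from_config <- function(x) {
  cfg <- if (file.exists(x)) yaml::read_yaml(x) else yaml::yaml.load(x)
  aa <- cfg$anatomy
  anatomy <- laa_anatomy(
    chamber_radii = as.numeric(aa$chamber_radii),
    pv_dirs = { m <- do.call(rbind, lapply(aa$pv_dirs, as.numeric))
                rownames(m) <- c("lupv", "llpv", "rupv", "rlpv"); m },
    pv_radius = aa$pv_radius, pv_length = aa$pv_length,
    mv_dir = as.numeric(aa$mv_dir), mv_radius = aa$mv_radius,
    mv_length = aa$mv_length, laa_dir = as.numeric(aa$laa_dir),
    laa_ostium_diameter = aa$laa_ostium_diameter, laa_depth = aa$laa_depth,
    laa_taper = aa$laa_taper, wall_resolution = aa$wall_resolution)
  device <- NULL
  if (!is.null(cfg$device)) {
    d <- cfg$device
    device <- laao_device(d$family, d$nominal_size,
                          deployed_diameter = d$deployed_diameter,
                          body_length = d$body_length,
                          disc_thickness = if (is.null(d$disc_thickness)) 4 else d$disc_thickness,
                          cove_radius = d$cove_radius, cove_depth = d$cove_depth,
                          shoulder_radius = d$shoulder_radius,
                          insert_radius = d$insert_radius,
                          insert_height = d$insert_height)
  }
  placement <- NULL
  if (!is.null(cfg$placement)) {
    p <- cfg$placement
    placement <- laa_placement(p$depth_offset, p$tilt, p$tilt_toward,
                               p$lateral_offset, p$lateral_toward)
  }
  wf <- cfg$waveform
  waveform <- af_waveform(wf$period, wf$s_amp, wf$s_phase, wf$s_width,
                          wf$d_amp, wf$d_phase, wf$d_width, wf$baseline,
                          as.numeric(wf$per_pv_scale))
  laa_scenario(cfg$name, anatomy, device, placement,
               fluid_properties(cfg$fluid$density, cfg$fluid$viscosity),
               waveform, cfg$roi_diameter)
}
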