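# Virtual implantation of appendage occluders.
#
# Two device families are modelled for the fluid domain only:
#   * non-pacifier (plug style, Watchman-like): capped cylinder seated inside
#     the appendage, with a rounded shoulder and a central cylindrical cove
#     (the threaded-insert recess) on the atrial face;
#   * pacifier (disc style, Amulet-like): thin disc covering the ostium with
#     a central protruding insert; the distal lobe is omitted because it is
#     sealed off from the blood pool and has no effect on the hemodynamics.
# Deployment is a geometric union with bounded wall accommodation: solid wall
# cells inside the expanded device are ceded to it, emulating penalty-free
# radial dilation of the tissue up to the deployed diameter.

#' Occluder device specification
#'
#' Deployed dimensions follow the manufacturer-labelled sizes: plug occluders
#' 27 and 24 deploy to 24 mm and 21.6 mm diameter (11 % and 10 % compression
#' in a matched landing zone); disc occluders 25 and 22 have disc diameters
#' of 32 mm and 28 mm. Cove, shoulder and insert dimensions are documented
#' model constants (not manufacturer data).
#'
#' @param family `"non_pacifier"` (plug) or `"pacifier"` (disc)
#' @param nominal_size labelled size in mm (plug: 27 or 24; disc: 25 or 22),
#'   or any size if all geometric fields are given explicitly
#' @param deployed_diameter plug body / disc diameter after deployment (mm)
#' @param body_length plug body length (mm); ignored for discs
#' @param disc_thickness disc thickness (mm); ignored for plugs
#' @param cove_radius,cove_depth central threaded-insert recess on the plug's
#'   atrial face (mm)
#' @param shoulder_radius rim rounding of the plug's atrial face (mm)
#' @param insert_radius,insert_height central insert protruding from the
#'   disc's atrial face (mm)
#' @return object of class `laao_device`
#' @export
laao_device <- function(family = c("non_pacifier", "pacifier"),
                        nominal_size,
                        deployed_diameter = NULL, body_length = NULL,
                        disc_thickness = 4,
                        cove_radius = 3.5, cove_depth = 2.5, shoulder_radius = 2,
                        insert_radius = 3, insert_height = 2.5) {
  family <- match.arg(family)
  presets <- list(
    non_pacifier = list(`27` = list(deployed_diameter = 24, body_length = 23),
                        `24` = list(deployed_diameter = 21.6, body_length = 20.5)),
    pacifier = list(`25` = list(deployed_diameter = 32),
                    `22` = list(deployed_diameter = 28))
  )
  key <- as.character(nominal_size)
  if (is.null(deployed_diameter)) {
    if (is.null(presets[[family]][[key]]))
      stop("no preset for ", family, " size ", key, "; give deployed_diameter explicitly")
    p <- presets[[family]][[key]]
    deployed_diameter <- p$deployed_diameter
    if (family == "non_pacifier" && is.null(body_length)) body_length <- p$body_length
  }
  if (family == "non_pacifier" && is.null(body_length)) body_length <- 0.85 * deployed_diameter
  stopifnot(deployed_diameter > 0, cove_radius < deployed_diameter / 2)
  structure(list(
    family = family, nominal_size = nominal_size,
    deployed_diameter = deployed_diameter,
    body_length = if (family == "non_pacifier") body_length else NULL,
    disc_thickness = if (family == "pacifier") disc_thickness else NULL,
    cove_radius = cove_radius, cove_depth = cove_depth,
    shoulder_radius = shoulder_radius,
    insert_radius = insert_radius, insert_height = insert_height
  ), class = "laao_device")
}

#' @export
print.laao_device <- function(x, ...) {
  cat("laao_device: ", x$family, " ", x$nominal_size,
      " (deployed diameter ", x$deployed_diameter, " mm)\n", sep = "")
  invisible(x)
}

# axial extent of the device's solid (distal closure plane), local frame
device_length <- function(device) {
  if (device$family == "non_pacifier") device$body_length else device$disc_thickness
}

#' Device placement
#'
#' The anchor is the centre of the device's atrial face, expressed through a
#' depth offset along the appendage axis from the ostium plane (0 = atrial
#' face in the ostium plane; negative = proximal/atrial side) plus an
#' optional in-plane lateral offset, and a tilt of the device axis away from
#' the appendage axis, toward either the mitral valve or the LUPV ridge.
#'
#' @param depth_offset mm along the LAA axis from the ostium plane
#' @param tilt degrees between device axis and LAA axis
#' @param tilt_toward `"mv"` or `"lupv"`: in-plane direction the device axis
#'   tips toward
#' @param lateral_offset mm of in-plane anchor shift (same direction rule)
#' @param lateral_toward `"mv"` or `"lupv"`
#' @return object of class `laa_placement`
#' @export
laa_placement <- function(depth_offset = 0, tilt = 0, tilt_toward = c("mv", "lupv"),
                          lateral_offset = 0, lateral_toward = c("mv", "lupv")) {
  structure(list(depth_offset = depth_offset, tilt = tilt,
                 tilt_toward = match.arg(tilt_toward),
                 lateral_offset = lateral_offset,
                 lateral_toward = match.arg(lateral_toward)),
            class = "laa_placement")
}

# in-plane unit vectors at the ostium: toward the LUPV anchor and toward the
# MV; both perpendicular to the appendage axis
ostium_frame <- function(anatomy) {
  ax <- anatomy$laa_dir
  proj <- function(v) {
    w <- v - sum(v * ax) * ax
    w / sqrt(sum(w^2))
  }
  list(axis = ax, to_lupv = proj(anatomy$pv_dirs["lupv", ]), to_mv = proj(anatomy$mv_dir))
}

# resolve a placement into anchor point + unit axis (mm, global frame)
placement_pose <- function(anatomy, placement) {
  op <- ostium_plane(anatomy)
  fr <- ostium_frame(anatomy)
  wdir <- function(which) if (which == "mv") fr$to_mv else fr$to_lupv
  a <- op$center + placement$depth_offset * fr$axis +
    placement$lateral_offset * wdir(placement$lateral_toward)
  tau <- placement$tilt * pi / 180
  d <- cos(tau) * fr$axis + sin(tau) * wdir(placement$tilt_toward)
  list(anchor = a, axis = d / sqrt(sum(d^2)))
}

# inside test for the device solid at points p (n x 3, mm)
device_inside <- function(device, pose, p) {
  rel <- sweep(p, 2, pose$anchor)
  z <- as.vector(rel %*% pose$axis)
  r <- sqrt(pmax(rowSums(rel^2) - z^2, 0))
  R <- device$deployed_diameter / 2
  if (device$family == "non_pacifier") {
    L <- device$body_length
    s <- device$shoulder_radius
    rmax <- ifelse(z < s, R - s + sqrt(pmax(s^2 - (s - z)^2, 0)), R)
    inside <- z >= 0 & z <= L & r <= rmax
    cove <- z >= 0 & z <= device$cove_depth & r <= device$cove_radius
    inside & !cove
  } else {
    td <- device$disc_thickness
    disc <- z >= 0 & z <= td & r <= R
    insert <- z >= -device$insert_height & z < 0 & r <= device$insert_radius
    disc | insert
  }
}

#' Deploy a device into a discretized anatomy
#'
#' Reclassifies grid cells inside the deployed device as device cells (solid
#' wall cells inside the device are ceded to it -- wall accommodation),
#' rebuilds boundary faces (fluid faces adjacent to the device become
#' `device_surface`), prunes fluid pockets sealed off from the outlet, and
#' computes the compression rate at the landing zone,
#' `1 - lumen_diameter / deployed_diameter`. A compression outside the
#' release criterion band 8--20 % raises a warning of class
#' `laaoflow_release_warning` (not an error).
#'
#' @param grid an `laa_grid` carrying its anatomy (from [discretize_anatomy()])
#' @param device an `laao_device`
#' @param placement an `laa_placement`
#' @return list: `grid` (updated), `compression_rate`, `sealed` (no fluid path
#'   into the appendage distal to the device), `pose`, `removed_volume` (mm^3
#'   of sealed-off pocket removed from the fluid domain)
#' @export
deploy <- function(grid, device, placement) {
  anatomy <- grid$anatomy
  if (is.null(anatomy)) stop("grid does not carry an anatomy; use discretize_anatomy()")
  pose <- placement_pose(anatomy, placement)
  op <- ostium_plane(anatomy)
  if (abs(sum(pose$axis * op$normal)) < 0.2)
    stop("device axis does not intersect the ostium plane region")

  dims <- grid$dims
  all_idx <- seq_len(prod(dims))
  ctr <- cell_centers_raw(all_idx, dims, grid$origin, grid$h)
  # only look near the device to keep the inside test cheap
  rel <- sweep(ctr, 2, pose$anchor)
  near <- rowSums(rel^2) <= (device$deployed_diameter / 2 + device_length(device) + 2 * grid$h)^2
  inside <- logical(prod(dims))
  inside[near] <- device_inside(device, pose, ctr[near, , drop = FALSE])

  cls <- grid$cell_class
  cls[inside] <- CELL_DEVICE
  classify <- anatomy_face_classifier(anatomy, grid$h)
  g2 <- grid_from_mask(cls == CELL_FLUID, grid$h, grid$origin, grid$periodic,
                       classify = classify, cell_class = cls)
  g2$anatomy <- anatomy
  g2 <- annotate_inflow(g2, anatomy)
  pr <- prune_disconnected(g2, classify)
  g2 <- pr$grid
  g2$anatomy <- anatomy
  g2 <- annotate_inflow(g2, anatomy)
  g2$device <- device
  g2$placement <- placement
  g2$pose <- pose

  # compression at the landing zone (device mid-body / disc distal face)
  z_anchor <- sum((pose$anchor - op$center) * op$normal)
  cosang <- sum(pose$axis * op$normal)
  z_land <- if (device$family == "non_pacifier") {
    z_anchor + cosang * device$body_length / 2
  } else {
    z_anchor + cosang * device$disc_thickness
  }
  lumen <- 2 * laa_lumen_radius(anatomy, max(z_land, 0))
  compression <- 1 - lumen / device$deployed_diameter
  if (compression < 0.08 || compression > 0.20) {
    warning(warningCondition(
      sprintf("compression rate %.3f outside the 8-20%% release criterion", compression),
      class = "laaoflow_release_warning"))
  }

  sealed <- !any_distal_fluid(g2, device, pose)
  list(grid = g2, compression_rate = compression, sealed = sealed,
       pose = pose, removed_volume = pr$n_removed * grid$cell_volume)
}

# fluid cells distal to the device's distal closure surface, inside the LAA
distal_fluid_mask <- function(grid, device, pose) {
  anatomy <- grid$anatomy
  ctr <- cell_centers(grid)
  rel <- sweep(ctr, 2, pose$anchor)
  z <- as.vector(rel %*% pose$axis)
  beyond <- z > device_length(device)
  in_laa <- sdf_laa(ctr, anatomy) < 0
  beyond & in_laa
}

any_distal_fluid <- function(grid, device, pose) {
  any(distal_fluid_mask(grid, device, pose))
}

#' Peri-device leak assessment
#'
#' Identifies the appendage lumen cells lying distal of both the ostium
#' plane and the device's atrial face (by more than one cell, so the rim
#' crevice at the shoulder is not counted) and summarizes the flow and
#' tracer exchange there. In a sealed deployment this region is empty or
#' stagnant; a peri-device gap shows fresh-blood ingress (concentration
#' below 1) and measurable speeds.
#'
#' @param grid a deployed `laa_grid` (with `pose`)
#' @param conc tracer concentration per fluid cell, or `NULL`
#' @param u n x 3 velocity (m/s), or `NULL`
#' @param margin distance (mm) beyond the atrial face to start counting
#' @return list: `n_cells`, `volume` (mm^3), `min_conc`, `max_speed`
#' @export
assess_leak <- function(grid, conc = NULL, u = NULL, margin = grid$h) {
  anatomy <- grid$anatomy
  pose <- grid$pose
  if (is.null(pose)) stop("grid has no deployed device")
  ctr <- cell_centers(grid)
  op <- ostium_plane(anatomy)
  z_ost <- as.vector(sweep(ctr, 2, op$center) %*% op$normal)
  z_dev <- as.vector(sweep(ctr, 2, pose$anchor) %*% pose$axis)
  region <- sdf_laa(ctr, anatomy) < 0 & z_ost > 0 & z_dev > margin
  list(
    n_cells = sum(region),
    volume = sum(region) * grid$cell_volume,
    min_conc = if (!is.null(conc) && any(region)) min(conc[region]) else NA_real_,
    max_speed = if (!is.null(u) && any(region))
      max(sqrt(rowSums(u[region, , drop = FALSE]^2))) else NA_real_
  )
}

#' Device position metrics
#'
#' Measured in the plane containing the appendage axis and the LUPV ridge
#' anchor (the analogue of the lower-middle transesophageal view with 90 deg
#' rotation):
#' * `lupv_ridge_length`: wall arc from the pulmonary-vein limbus (ostium rim
#'   point nearest the LUPV) to the device's atrial rim on the ridge side;
#' * `implant_depth_mv`: the symmetric counterpart measured on the
#'   mitral-valve side of the rim (depth of the atrial rim toward the MV);
#' * `device_ridge_angle`: angle alpha between the device axis and the ridge
#'   tangent (taken antiparallel to the appendage axis at the limbus), so an
#'   untilted device reads 180 deg;
#' * `deep_flag`: deep implantation, LUPV ridge length > 10 mm.
#'
#' @param anatomy an `laa_anatomy`
#' @param device an `laao_device`
#' @param placement an `laa_placement`
#' @param compression_rate optional passthrough from [deploy()]
#' @return object of class `laa_position_metrics` (a named list)
#' @export
measure_position <- function(anatomy, device, placement, compression_rate = NA_real_) {
  pose <- placement_pose(anatomy, placement)
  op <- ostium_plane(anatomy)
  fr <- ostium_frame(anatomy)
  R <- device$deployed_diameter / 2
  slope <- (1 - anatomy$laa_taper) * (anatomy$laa_ostium_diameter / 2) / anatomy$laa_depth
  arc <- sqrt(1 + slope^2)

  rim_depth <- function(wdir) {
    e <- wdir - sum(wdir * pose$axis) * pose$axis
    e <- e / sqrt(sum(e^2))
    p_rim <- pose$anchor + R * e
    sum((p_rim - op$center) * op$normal)
  }
  z_ridge <- rim_depth(fr$to_lupv)
  z_mv <- rim_depth(fr$to_mv)
  z_center <- sum((pose$anchor - op$center) * op$normal)
  proximal <- z_ridge <= 0 && z_center <= 0

  # in-plane tilt: angle of the device axis projected into the measurement
  # plane (spanned by the LAA axis and the LUPV direction)
  b2 <- fr$to_lupv
  d_ip <- sum(pose$axis * fr$axis) * fr$axis + sum(pose$axis * b2) * b2
  d_ip <- d_ip / sqrt(sum(d_ip^2))
  tilt_ip <- acos(pmin(1, pmax(-1, sum(d_ip * fr$axis)))) * 180 / pi
  alpha <- 180 - tilt_ip

  structure(list(
    lupv_ridge_length = max(0, z_ridge) * arc,
    implant_depth_mv = max(0, z_mv) * arc,
    device_ridge_angle = alpha,
    compression_rate = compression_rate,
    deep_flag = max(0, z_ridge) * arc > 10,
    proximal_flag = proximal
  ), class = "laa_position_metrics")
}

#' @export
print.laa_position_metrics <- function(x, ...) {
  cat(sprintf("LUPV ridge length: %.1f mm%s%s\n", x$lupv_ridge_length,
              if (x$deep_flag) " (deep implantation)" else "",
              if (x$proximal_flag) " (proximal)" else ""))
  cat(sprintf("implant depth toward MV: %.1f mm\n", x$implant_depth_mv))
  cat(sprintf("device-ridge angle alpha: %.1f deg\n", x$device_ridge_angle))
  if (is.finite(x$compression_rate))
    cat(sprintf("compression rate: %.1f %%\n", 100 * x$compression_rate))
  invisible(x)
}

#' Placement depth for a target LUPV ridge length
#'
#' Inverts the ridge-length measurement for an untilted, centred placement:
#' the atrial rim must sit at depth `target / sqrt(1 + slope^2)` along the
#' appendage axis, where `slope` is the wall taper.
#'
#' @param anatomy an `laa_anatomy`
#' @param target desired ridge length (mm)
#' @return depth offset (mm) for [laa_placement()]
#' @export
depth_for_ridge <- function(anatomy, target) {
  slope <- (1 - anatomy$laa_taper) * (anatomy$laa_ostium_diameter / 2) / anatomy$laa_depth
  target / sqrt(1 + slope^2)
}

#' Region of interest around the device's atrial face
#'
#' All fluid cells within a sphere (default diameter 40 mm) centred on the
#' LAA ostium midpoint, excluding the appendage region distal to the device's
#' distal closure surface. Pre-occlusion (no device) there is no exclusion.
#'
#' @param grid an `laa_grid`
#' @param device,placement the deployed device, or `NULL` pre-occlusion
#' @param diameter ROI sphere diameter (mm)
#' @return list: `mask` (logical over fluid cells), `center`, `diameter`,
#'   `volume` (mm^3), `excluded` (logical: distal-to-device cells in sphere)
#' @export
build_roi <- function(grid, device = NULL, placement = NULL, diameter = 40) {
  anatomy <- grid$anatomy
  center <- if (!is.null(anatomy)) ostium_plane(anatomy)$center else c(0, 0, 0)
  ctr <- cell_centers(grid)
  rel <- sweep(ctr, 2, center)
  in_sphere <- rowSums(rel^2) <= (diameter / 2)^2
  excl <- rep(FALSE, grid$n_fluid)
  if (!is.null(device)) {
    pose <- if (!is.null(grid$pose)) grid$pose else placement_pose(anatomy, placement)
    excl <- distal_fluid_mask(grid, device, pose)
  }
  mask <- in_sphere & !excl
  if (!any(mask)) stop("configuration error: ROI is empty")
  list(mask = mask, center = center, diameter = diameter,
       volume = sum(mask) * grid$cell_volume, excluded = in_sphere & excl)
}
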