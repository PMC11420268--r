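# Parametric left atrium / left atrial appendage anatomy.
#
# The chamber is an ellipsoid; the four pulmonary veins (PVs) and the mitral
# outlet are straight tubes grafted radially onto it; the appendage (LAA) is a
# tapered cone with a rounded apex grafted at the ostium. All solids are
# represented implicitly (signed distance < 0 inside, in mm) and the fluid
# domain is their union, voxelized on a uniform grid.

#' Parametric LA/LAA anatomy
#'
#' Creates the parameter set describing a synthetic left atrium with four
#' pulmonary-vein inlet tubes, one mitral outlet tube and a tapered left
#' atrial appendage. Defaults are sized so the LAA ostium accepts a 27 mm
#' plug occluder (deployed diameter 24 mm) within the 8--20 % compression
#' release criterion, and so peak tube Reynolds numbers stay laminar.
#'
#' @param chamber_radii ellipsoid semi-axes (mm)
#' @param pv_dirs 4 x 3 matrix of unit directions of the pulmonary veins
#'   (rows: LUPV, LLPV, RUPV, RLPV)
#' @param pv_radius PV tube radius (mm)
#' @param pv_length PV tube length beyond the chamber wall (mm)
#' @param mv_dir unit direction of the mitral outlet tube
#' @param mv_radius mitral tube radius (mm); the default matches a typical
#'   25 mm mitral annulus
#' @param mv_length mitral outlet tube length (mm)
#' @param laa_dir unit direction of the appendage axis
#' @param laa_ostium_diameter ostium diameter (mm)
#' @param laa_depth appendage depth along its axis (mm)
#' @param laa_taper apex/ostium radius ratio in (0, 1]
#' @param wall_resolution target surface edge length (mm)
#' @return object of class `laa_anatomy`
#' @export
laa_anatomy <- function(chamber_radii = c(30, 26, 24),
                        pv_dirs = rbind(
                          lupv = c(0.30, 0.25, 0.92),
                          llpv = c(0.60, 0.62, -0.50),
                          rupv = c(-0.62, 0.42, 0.66),
                          rlpv = c(-0.70, 0.55, -0.45)),
                        pv_radius = 6, pv_length = 30,
                        mv_dir = c(0.10, -0.90, -0.42),
                        mv_radius = 12.5, mv_length = 10,
                        laa_dir = c(0.90, -0.12, 0.42),
                        laa_ostium_diameter = 24,
                        laa_depth = 34,
                        laa_taper = 0.675,
                        wall_resolution = 2.0) {
  unit <- function(v) v / sqrt(sum(v^2))
  pv_dirs <- t(apply(pv_dirs, 1, unit))
  mv_dir <- unit(mv_dir)
  laa_dir <- unit(laa_dir)
  a <- structure(list(
    chamber_radii = chamber_radii,
    pv_dirs = pv_dirs, pv_radius = pv_radius, pv_length = pv_length,
    mv_dir = mv_dir, mv_radius = mv_radius, mv_length = mv_length,
    laa_dir = laa_dir, laa_ostium_diameter = laa_ostium_diameter,
    laa_depth = laa_depth, laa_taper = laa_taper,
    wall_resolution = wall_resolution
  ), class = "laa_anatomy")
  validate_anatomy(a)
  a
}

validate_anatomy <- function(a) {
  lens <- c(a$chamber_radii, a$pv_radius, a$pv_length, a$mv_radius,
            a$mv_length, a$laa_ostium_diameter, a$laa_depth, a$wall_resolution)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("anatomy error: all lengths must be positive (got a degenerate length)")
  if (a$laa_taper <= 0 || a$laa_taper > 1)
    stop("anatomy error: laa_taper must lie in (0, 1]")
  if (a$laa_ostium_diameter >= 2 * min(a$chamber_radii))
    stop("anatomy error: LAA ostium wider than the chamber")
  # tubes and appendage must not mutually intersect: check the angular
  # separation of their graft directions against their angular footprints
  dirs <- rbind(a$pv_dirs, mv = a$mv_dir, laa = a$laa_dir)
  rad <- c(rep(a$pv_radius, 4), a$mv_radius, a$laa_ostium_diameter / 2)
  rmin <- min(a$chamber_radii)
  half_ang <- asin(pmin(1, rad / rmin))
  nm <- rownames(dirs)
  for (i in 1:(nrow(dirs) - 1)) for (j in (i + 1):nrow(dirs)) {
    ang <- acos(pmin(1, pmax(-1, sum(dirs[i, ] * dirs[j, ]))))
    if (ang < half_ang[i] + half_ang[j])
      stop(sprintf("geometry error: tubes '%s' and '%s' intersect (separation %.1f deg < %.1f deg)",
                   nm[i], nm[j], ang * 180 / pi, (half_ang[i] + half_ang[j]) * 180 / pi))
  }
  invisible(a)
}

# point on the ellipsoid surface along unit direction u (from centre)
ellipsoid_point <- function(radii, u) {
  t <- 1 / sqrt(sum((u / radii)^2))
  t * u
}

#' LAA ostium plane
#' @param anatomy an `laa_anatomy`
#' @return list(center, normal): ostium centre (mm) and unit normal
#'   (pointing into the appendage, along the LAA axis)
#' @export
ostium_plane <- function(anatomy) {
  list(center = ellipsoid_point(anatomy$chamber_radii, anatomy$laa_dir),
       normal = anatomy$laa_dir)
}

#' LAA lumen radius at a given depth
#'
#' Radius of the (conical) appendage lumen at depth `z` along the LAA axis
#' from the ostium plane; the apex is rounded so the radius falls smoothly
#' to zero at `laa_depth`.
#'
#' @param anatomy an `laa_anatomy`
#' @param z depth (mm) from the ostium plane, >= 0
#' @return lumen radius (mm); 0 beyond the apex
#' @export
laa_lumen_radius <- function(anatomy, z) {
  r0 <- anatomy$laa_ostium_diameter / 2
  rap <- r0 * anatomy$laa_taper
  L <- anatomy$laa_depth
  r <- r0 + (rap - r0) * pmin(pmax(z, 0), L) / L
  # rounded apex: spherical cap of radius rap centred at depth L - rap... keep
  # the cone down to depth L, then a hemispherical cap of radius rap
  cap <- z > L
  r[cap] <- rap * sqrt(pmax(0, 1 - ((z[cap] - L) / rap)^2))
  r[z > L + rap] <- 0
  r
}

# signed distance functions (approximate for the ellipsoid; sign-exact)
sdf_ellipsoid <- function(p, radii) {
  q <- sqrt((p[, 1] / radii[1])^2 + (p[, 2] / radii[2])^2 + (p[, 3] / radii[3])^2)
  (q - 1) * min(radii)
}

# finite tube along unit direction d from base point b, length L, radius r;
# open at the base (the chamber fills it), capped (flat) at the far end
sdf_tube <- function(p, b, d, L, r) {
  rel <- sweep(p, 2, b)
  t <- rel %*% d
  rad2 <- rowSums(rel^2) - t^2
  radial <- sqrt(pmax(rad2, 0)) - r
  axial <- pmax(-t, t - L)           # negative inside [0, L]
  pmax(radial, axial)
}

# tapered appendage from the ostium plane: local radius laa_lumen_radius(z)
sdf_laa <- function(p, anatomy) {
  op <- ostium_plane(anatomy)
  rel <- sweep(p, 2, op$center)
  z <- as.vector(rel %*% op$normal)
  rad <- sqrt(pmax(rowSums(rel^2) - z^2, 0))
  rr <- laa_lumen_radius(anatomy, pmax(z, 0))
  radial <- rad - rr
  axial <- pmax(-z, z - (anatomy$laa_depth + anatomy$laa_ostium_diameter / 2 * anatomy$laa_taper))
  pmax(radial, axial)
}

#' Signed distance of the full fluid domain
#'
#' Union (pointwise minimum) of the chamber ellipsoid, the five tubes and the
#' appendage; negative inside the blood pool.
#'
#' @param anatomy an `laa_anatomy`
#' @param p n x 3 matrix of points (mm)
#' @return signed distance per point (mm; sign-exact, magnitude approximate)
#' @export
anatomy_sdf <- function(anatomy, p) {
  p <- rbind(p)  # tolerate a single point as a vector
  if (is.null(dim(p)) || ncol(p) != 3) p <- matrix(p, ncol = 3)
  s <- sdf_ellipsoid(p, anatomy$chamber_radii)
  for (i in 1:4) {
    b <- ellipsoid_point(anatomy$chamber_radii, anatomy$pv_dirs[i, ])
    s <- pmin(s, sdf_tube(p, b, anatomy$pv_dirs[i, ], anatomy$pv_length, anatomy$pv_radius))
  }
  bm <- ellipsoid_point(anatomy$chamber_radii, anatomy$mv_dir)
  s <- pmin(s, sdf_tube(p, bm, anatomy$mv_dir, anatomy$mv_length, anatomy$mv_radius))
  s <- pmin(s, sdf_laa(p, anatomy))
  s
}

#' Ridge anchor: ostium rim point nearest the LUPV (the pulmonary-vein limbus)
#' @param anatomy an `laa_anatomy`
#' @return point (mm) on the ostium rim
#' @export
lupv_ridge_anchor <- function(anatomy) {
  op <- ostium_plane(anatomy)
  m <- anatomy$pv_dirs["lupv", ] - sum(anatomy$pv_dirs["lupv", ] * op$normal) * op$normal
  m <- m / sqrt(sum(m^2))
  op$center + (anatomy$laa_ostium_diameter / 2) * m
}

#' @export
print.laa_anatomy <- function(x, ...) {
  cat("laa_anatomy\n")
  cat("  chamber semi-axes:", paste(x$chamber_radii, collapse = " x "), "mm\n")
  cat("  PV tubes: r =", x$pv_radius, "mm, L =", x$pv_length, "mm;  MV tube: r =",
      x$mv_radius, "mm, L =", x$mv_length, "mm\n")
  cat("  LAA: ostium", x$laa_ostium_diameter, "mm, depth", x$laa_depth,
      "mm, taper", x$laa_taper, "\n")
  invisible(x)
}

#' Voxelize an anatomy onto a uniform grid
#'
#' Discretizes the implicit fluid domain: cell centres with negative signed
#' distance become fluid; boundary faces are classified as `wall`,
#' `pv_inlet_1..4` (tube end caps) or `mv_outlet`.
#'
#' @param anatomy an `laa_anatomy`
#' @param h cell size (mm); defaults to `wall_resolution`
#' @param margin padding around the bounding box (mm)
#' @return an `laa_grid`
#' @export
discretize_anatomy <- function(anatomy, h = anatomy$wall_resolution, margin = 2) {
  if (min(anatomy$pv_radius, anatomy$mv_radius) / h < 1.5)
    stop("resolution error: tube cross-sections need at least 3 cells across; reduce h")
  bb <- anatomy_bbox(anatomy, margin)
  dims <- pmax(2L, as.integer(ceiling((bb$hi - bb$lo) / h)))
  origin <- bb$lo
  ctr <- expand_centers(dims, origin, h)
  inside <- anatomy_sdf(anatomy, ctr) < 0
  mask <- fix_pinch(array(inside, dim = dims))
  classify <- anatomy_face_classifier(anatomy, h)
  g <- grid_from_mask(mask, h, origin, classify = classify)
  g$anatomy <- anatomy
  pr <- prune_disconnected(g, classify)
  g <- pr$grid
  g$anatomy <- anatomy
  # labelling completeness: each tube end must expose at least one face
  pt <- table(factor(g$bfaces$patch,
                     levels = c(paste0("pv_inlet_", 1:4), "mv_outlet")))
  if (any(pt == 0))
    stop("resolution error: tube end caps unresolved: ",
         paste(names(pt)[pt == 0], collapse = ", "))
  g <- annotate_inflow(g, anatomy)
  g
}

# per-inlet-face inflow direction (the tube axis) and projection factor
# normal . axis, so that the staircase cap carries the correct volume flux
annotate_inflow <- function(grid, anatomy) {
  bf <- grid$bfaces
  bf$scale <- ifelse(bf$bc_type == "inlet", 0, NA_real_)
  bf$bdir1 <- NA_real_; bf$bdir2 <- NA_real_; bf$bdir3 <- NA_real_
  for (i in 1:4) {
    sel <- bf$patch == paste0("pv_inlet_", i)
    if (!any(sel)) next
    d <- -anatomy$pv_dirs[i, ]    # inflow points back down the tube
    nrm <- DIR_VECS[bf$dir[sel], , drop = FALSE]
    bf$scale[sel] <- pmax(0, -(nrm %*% d))
    bf$bdir1[sel] <- d[1]; bf$bdir2[sel] <- d[2]; bf$bdir3[sel] <- d[3]
  }
  grid$bfaces <- bf
  grid
}

anatomy_bbox <- function(anatomy, margin = 2) {
  lo <- -anatomy$chamber_radii
  hi <- anatomy$chamber_radii
  add <- function(lo, hi, pts) list(lo = pmin(lo, apply(pts, 2, min)),
                                    hi = pmax(hi, apply(pts, 2, max)))
  for (i in 1:4) {
    b <- ellipsoid_point(anatomy$chamber_radii, anatomy$pv_dirs[i, ])
    e <- b + anatomy$pv_length * anatomy$pv_dirs[i, ]
    bb <- add(lo, hi, rbind(e + anatomy$pv_radius, e - anatomy$pv_radius))
    lo <- bb$lo; hi <- bb$hi
  }
  bm <- ellipsoid_point(anatomy$chamber_radii, anatomy$mv_dir)
  em <- bm + anatomy$mv_length * anatomy$mv_dir
  bb <- add(lo, hi, rbind(em + anatomy$mv_radius, em - anatomy$mv_radius))
  lo <- bb$lo; hi <- bb$hi
  op <- ostium_plane(anatomy)
  ea <- op$center + (anatomy$laa_depth + anatomy$laa_ostium_diameter / 2) * op$normal
  bb <- add(lo, hi, rbind(ea + anatomy$laa_ostium_diameter / 2,
                          ea - anatomy$laa_ostium_diameter / 2))
  list(lo = bb$lo - margin, hi = bb$hi + margin)
}

expand_centers <- function(dims, origin, h) {
  x <- origin[1] + (seq_len(dims[1]) - 0.5) * h
  y <- origin[2] + (seq_len(dims[2]) - 0.5) * h
  z <- origin[3] + (seq_len(dims[3]) - 0.5) * h
  cbind(rep(x, times = dims[2] * dims[3]),
        rep(rep(y, each = dims[1]), times = dims[3]),
        rep(z, each = dims[1] * dims[2]))
}

# face classifier: tube end caps become inlets/outlet, everything else wall.
# A boundary face belongs to a tube cap if it lies inside the tube's
# cross-section, near the cap plane, and its outward normal points along the
# tube axis.
anatomy_face_classifier <- function(anatomy, h) {
  ends <- vector("list", 5)
  for (i in 1:4) {
    b <- ellipsoid_point(anatomy$chamber_radii, anatomy$pv_dirs[i, ])
    ends[[i]] <- list(p = b + anatomy$pv_length * anatomy$pv_dirs[i, ],
                      d = anatomy$pv_dirs[i, ], r = anatomy$pv_radius,
                      label = paste0("pv_inlet_", i))
  }
  bm <- ellipsoid_point(anatomy$chamber_radii, anatomy$mv_dir)
  ends[[5]] <- list(p = bm + anatomy$mv_length * anatomy$mv_dir,
                    d = anatomy$mv_dir, r = anatomy$mv_radius, label = "mv_outlet")
  function(centers, dir) {
    lab <- rep("wall", nrow(centers))
    nrm <- DIR_VECS[dir, ]
    for (e in ends) {
      if (sum(nrm * e$d) < 0.2) next
      rel <- sweep(centers, 2, e$p)
      t <- as.vector(rel %*% e$d)
      rad <- sqrt(pmax(rowSums(rel^2) - t^2, 0))
      hit <- rad <= e$r & t > -1.5 * h & t < 1.5 * h
      lab[hit] <- e$label
    }
    lab
  }
}
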