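# Watertight voxel surface of the fluid domain, patch labels, STL I/O.
#
# The surface is the set of boundary quads between fluid and non-fluid cells
# of a voxelized domain. It is closed and consistently oriented by
# construction; `check_watertight()` verifies the edge-manifold property
# (every edge shared by exactly two faces).

#' Extract the boundary surface of a grid
#'
#' @param grid an `laa_grid`
#' @return object of class `laa_surface`: vertex matrix (mm), quad index
#'   matrix (outward-oriented), per-quad patch label and outward normal
#' @export
build_surface <- function(grid) {
  bf <- grid$bfaces
  h <- grid$h
  ctr <- cell_centers(grid, grid$fluid_idx[bf$cell])
  n <- nrow(bf)
  # quad corners: for a face in direction d, the 4 voxel corners of that face
  verts <- matrix(0, 4 * n, 3)
  quads <- matrix(0L, n, 4)
  for (d in 1:6) {
    sel <- which(bf$dir == d)
    if (!length(sel)) next
    nrm <- DIR_VECS[d, ]
    ax <- DIR_AXIS[d]
    t1 <- c(2, 3, 1)[ax]; t2 <- c(3, 1, 2)[ax]
    e1 <- numeric(3); e1[t1] <- h / 2
    e2 <- numeric(3); e2[t2] <- h / 2
    fc <- ctr[sel, , drop = FALSE] + matrix(nrm * h / 2, length(sel), 3, byrow = TRUE)
    # order corners so the quad winds counter-clockwise seen from outside
    s <- if (DIR_SIGN[d] > 0) 1 else -1
    corners <- list(-e1 - e2, s * e1 - s * e2, e1 + e2, -s * e1 + s * e2)
    for (ci in 1:4) {
      verts[4 * (sel - 1) + ci, ] <- fc + matrix(corners[[ci]], length(sel), 3, byrow = TRUE)
    }
    quads[sel, ] <- cbind(4L * (sel - 1L) + 1L, 4L * (sel - 1L) + 2L,
                          4L * (sel - 1L) + 3L, 4L * (sel - 1L) + 4L)
  }
  # merge duplicate vertices so shared edges are identifiable
  key <- paste(round(verts[, 1] / h * 2), round(verts[, 2] / h * 2),
               round(verts[, 3] / h * 2))
  uid <- match(key, key[!duplicated(key)])
  vkeep <- verts[!duplicated(key), , drop = FALSE]
  quads[] <- uid[quads]
  structure(list(
    vertices = vkeep, quads = quads, patch = bf$patch,
    normals = DIR_VECS[bf$dir, , drop = FALSE],
    h = h, grid = NULL
  ), class = "laa_surface")
}

#' Edge-manifold / watertightness check
#'
#' @param surface an `laa_surface`
#' @return list(watertight, n_bad_edges): `watertight` is TRUE when every
#'   edge is shared by exactly two faces
#' @export
check_watertight <- function(surface) {
  q <- surface$quads
  edges <- rbind(
    cbind(q[, 1], q[, 2]), cbind(q[, 2], q[, 3]),
    cbind(q[, 3], q[, 4]), cbind(q[, 4], q[, 1])
  )
  ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  cnt <- table(ekey)
  bad <- sum(cnt != 2)
  list(watertight = bad == 0L, n_bad_edges = bad)
}

#' Enclosed volume of a closed surface
#'
#' Divergence-theorem sum over the oriented quads.
#'
#' @param surface an `laa_surface`
#' @return volume (mm^3)
#' @export
surface_volume <- function(surface) {
  v <- surface$vertices
  q <- surface$quads
  # centroid x-coordinate times projected x-area per quad
  fc_x <- (v[q[, 1], 1] + v[q[, 2], 1] + v[q[, 3], 1] + v[q[, 4], 1]) / 4
  ax <- surface$normals[, 1] * surface$h^2
  sum(fc_x * ax)
}

#' Build the labelled anatomy surface
#'
#' Voxelizes the anatomy at its `wall_resolution` and extracts the closed
#' boundary surface with patch labels (`wall`, `pv_inlet_1..4`, `mv_outlet`).
#' The LAA ostium plane is attached as an attribute.
#'
#' @param anatomy an `laa_anatomy`
#' @param h surface voxel size (mm); defaults to `wall_resolution`
#' @return an `laa_surface`
#' @export
build_anatomy_surface <- function(anatomy, h = anatomy$wall_resolution) {
  if (anatomy$laa_depth <= 0)
    stop("geometry error: appendage degenerate (laa_depth must be > 0)")
  g <- discretize_anatomy(anatomy, h)
  s <- build_surface(g)
  s$ostium <- ostium_plane(anatomy)
  s$anatomy <- anatomy
  s
}

#' @export
print.laa_surface <- function(x, ...) {
  cat("laa_surface: ", nrow(x$quads), " quads, ", nrow(x$vertices), " vertices\n", sep = "")
  tb <- table(x$patch)
  cat("  patches:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  wt <- check_watertight(x)
  cat("  watertight:", wt$watertight, "\n")
  invisible(x)
}

#' Write a surface to ASCII STL
#'
#' Each quad is split into two triangles. Patch labels are not representable
#' in STL and are dropped.
#'
#' @param surface an `laa_surface`
#' @param path output file
#' @export
write_stl <- function(surface, path) {
  v <- surface$vertices
  q <- surface$quads
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid laaoflow", con)
  tri <- rbind(q[, c(1, 2, 3)], q[, c(1, 3, 4)])
  nrm <- rbind(surface$normals, surface$normals)
  out <- character(nrow(tri) * 7)
  k <- 0L
  for (i in seq_len(nrow(tri))) {
    out[k + 1] <- sprintf("  facet normal %g %g %g", nrm[i, 1], nrm[i, 2], nrm[i, 3])
    out[k + 2] <- "    outer loop"
    out[k + 3] <- sprintf("      vertex %g %g %g", v[tri[i, 1], 1], v[tri[i, 1], 2], v[tri[i, 1], 3])
    out[k + 4] <- sprintf("      vertex %g %g %g", v[tri[i, 2], 1], v[tri[i, 2], 2], v[tri[i, 2], 3])
    out[k + 5] <- sprintf("      vertex %g %g %g", v[tri[i, 3], 1], v[tri[i, 3], 2], v[tri[i, 3], 3])
    out[k + 6] <- "    endloop"
    out[k + 7] <- "  endfacet"
    k <- k + 7L
  }
  writeLines(out, con)
  writeLines("endsolid laaoflow", con)
  invisible(path)
}

#' Read an ASCII STL file
#'
#' @param path STL file
#' @return list(vertices, triangles) in the file's units
#' @export
read_stl <- function(path) {
  ln <- readLines(path)
  vl <- grep("^\\s*vertex", ln, value = TRUE)
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x) as.numeric(x[2:4])))
  ntri <- nrow(nums) / 3
  if (ntri != floor(ntri)) stop("malformed STL: vertex count not a multiple of 3")
  key <- paste(nums[, 1], nums[, 2], nums[, 3])
  uid <- match(key, key[!duplicated(key)])
  verts <- nums[!duplicated(key), , drop = FALSE]
  tris <- matrix(uid, ncol = 3, byrow = TRUE)
  list(vertices = verts, triangles = tris)
}

#' Voxelize a closed triangle surface (STL import path)
#'
#' Inside/outside by ray-casting parity along +z for each (x, y) cell column.
#' This is the optional route for externally produced chamber surfaces in
#' place of the parametric generator.
#'
#' @param stl list(vertices, triangles) as from [read_stl()]
#' @param h cell size (same units as the STL)
#' @param margin bounding-box padding
#' @param classify optional boundary-face classifier (see [grid_from_mask()])
#' @return an `laa_grid`
#' @export
voxelize_stl <- function(stl, h, margin = 2 * h, classify = NULL) {
  v <- stl$vertices; tr <- stl$triangles
  lo <- apply(v, 2, min) - margin
  hi <- apply(v, 2, max) + margin
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / h)))
  xs <- lo[1] + (seq_len(dims[1]) - 0.5) * h
  ys <- lo[2] + (seq_len(dims[2]) - 0.5) * h
  zs <- lo[3] + (seq_len(dims[3]) - 0.5) * h
  mask <- array(FALSE, dim = dims)
  a <- v[tr[, 1], , drop = FALSE]; b <- v[tr[, 2], , drop = FALSE]; cc <- v[tr[, 3], , drop = FALSE]
  # tiny deterministic ray offset so rays never pass exactly through
  # triangle edges or vertices (degenerate parity) on axis-aligned meshes
  ex <- 1.73e-4 * h; ey <- 1.31e-4 * h
  for (ix in seq_len(dims[1])) for (iy in seq_len(dims[2])) {
    px <- xs[ix] + ex; py <- ys[iy] + ey
    # 2d point-in-triangle test in the xy plane, then z of the hit
    d1 <- (b[, 1] - a[, 1]) * (py - a[, 2]) - (b[, 2] - a[, 2]) * (px - a[, 1])
    d2 <- (cc[, 1] - b[, 1]) * (py - b[, 2]) - (cc[, 2] - b[, 2]) * (px - b[, 1])
    d3 <- (a[, 1] - cc[, 1]) * (py - cc[, 2]) - (a[, 2] - cc[, 2]) * (px - cc[, 1])
    hit <- which((d1 >= 0 & d2 >= 0 & d3 >= 0) | (d1 <= 0 & d2 <= 0 & d3 <= 0))
    if (!length(hit)) next
    zhit <- numeric(0)
    for (t in hit) {
      # barycentric interpolation of z at (px, py)
      den <- (b[t, 2] - cc[t, 2]) * (a[t, 1] - cc[t, 1]) + (cc[t, 1] - b[t, 1]) * (a[t, 2] - cc[t, 2])
      if (abs(den) < 1e-12) next
      w1 <- ((b[t, 2] - cc[t, 2]) * (px - cc[t, 1]) + (cc[t, 1] - b[t, 1]) * (py - cc[t, 2])) / den
      w2 <- ((cc[t, 2] - a[t, 2]) * (px - cc[t, 1]) + (a[t, 1] - cc[t, 1]) * (py - cc[t, 2])) / den
      w3 <- 1 - w1 - w2
      zhit <- c(zhit, w1 * a[t, 3] + w2 * b[t, 3] + w3 * cc[t, 3])
    }
    if (!length(zhit)) next
    zhit <- sort(zhit)
    inside <- vapply(zs, function(z) (sum(zhit < z) %% 2) == 1L, logical(1))
    mask[ix, iy, ] <- inside
  }
  grid_from_mask(mask, h, origin = lo, classify = classify)
}
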