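# Uniform Cartesian voxel grid for the fluid domain.
#
# Cells are classified solid (0), fluid (1) or device (2). The solver works on
# the vector of fluid cells; geometry stays in mm, the solver converts to SI.
# Directions are indexed 1..6 = +x,-x,+y,-y,+z,-z.

DIR_VECS <- rbind(
  c(1L, 0L, 0L), c(-1L, 0L, 0L),
  c(0L, 1L, 0L), c(0L, -1L, 0L),
  c(0L, 0L, 1L), c(0L, 0L, -1L)
)
DIR_AXIS <- c(1L, 1L, 2L, 2L, 3L, 3L)
DIR_SIGN <- c(1, -1, 1, -1, 1, -1)
DIR_OPP  <- c(2L, 1L, 4L, 3L, 6L, 5L)

CELL_SOLID  <- 0L
CELL_FLUID  <- 1L
CELL_DEVICE <- 2L

#' Cell centre coordinates of a grid
#'
#' @param grid an `laa_grid`
#' @param idx linear cell indices (default: all fluid cells)
#' @return matrix (n x 3) of cell-centre coordinates in mm
#' @export
cell_centers <- function(grid, idx = grid$fluid_idx) {
  d <- grid$dims
  i <- (idx - 1L) %% d[1]
  j <- ((idx - 1L) %/% d[1]) %% d[2]
  k <- (idx - 1L) %/% (d[1] * d[2])
  cbind(
    grid$origin[1] + (i + 0.5) * grid$h,
    grid$origin[2] + (j + 0.5) * grid$h,
    grid$origin[3] + (k + 0.5) * grid$h
  )
}

# linear index from 0-based (i,j,k); no bounds check
lin_index <- function(i, j, k, dims) 1L + i + dims[1] * (j + dims[2] * k)

# neighbour linear index in direction d with optional periodic wrap;
# returns NA for out-of-bounds non-periodic
neighbor_lin <- function(idx, d, dims, periodic) {
  i <- (idx - 1L) %% dims[1]
  j <- ((idx - 1L) %/% dims[1]) %% dims[2]
  k <- (idx - 1L) %/% (dims[1] * dims[2])
  v <- DIR_VECS[d, ]
  i <- i + v[1]; j <- j + v[2]; k <- k + v[3]
  ax <- DIR_AXIS[d]
  coords <- list(i, j, k)
  cc <- coords[[ax]]
  out <- cc < 0L | cc >= dims[ax]
  if (periodic[ax]) {
    coords[[ax]] <- cc %% dims[ax]
    out[] <- FALSE
  }
  res <- lin_index(coords[[1]], coords[[2]], coords[[3]], dims)
  res[out] <- NA_integer_
  res
}

#' Build a grid from a fluid mask
#'
#' Constructs the discrete fluid domain used by the flow solver: per-fluid-cell
#' neighbour tables, boundary faces with outward normals and a boundary-
#' condition type per face. `classify` maps boundary-face centres to patch
#' labels; anything it does not label is a no-slip wall.
#'
#' @param mask logical 3d array, `TRUE` = fluid
#' @param h cell size (mm)
#' @param origin corner of cell (1,1,1) (mm)
#' @param periodic logical length-3: periodic wrap per axis (benchmark boxes)
#' @param classify `function(centers, dir)` returning a character patch label
#'   per face (centres in mm, `dir` in 1..6), or `NULL` for all-wall
#' @param cell_class optional integer array (same shape as `mask`) with device
#'   cells marked `2L`
#' @return an object of class `laa_grid`
#' @export
grid_from_mask <- function(mask, h, origin = c(0, 0, 0), periodic = c(FALSE, FALSE, FALSE),
                           classify = NULL, cell_class = NULL) {
  dims <- dim(mask)
  stopifnot(length(dims) == 3L, h > 0)
  if (is.null(cell_class)) {
    cell_class <- array(ifelse(mask, CELL_FLUID, CELL_SOLID), dim = dims)
  }
  fluid_idx <- which(cell_class == CELL_FLUID)
  n <- length(fluid_idx)
  if (n == 0L) stop("grid has no fluid cells")
  cmap <- integer(prod(dims))
  cmap[fluid_idx] <- seq_len(n)

  nbr <- matrix(0L, n, 6)         # fluid ordinal of neighbour, 0 if not fluid
  nbr_lin <- matrix(NA_integer_, n, 6)
  for (d in 1:6) {
    nl <- neighbor_lin(fluid_idx, d, dims, periodic)
    nbr_lin[, d] <- nl
    ok <- !is.na(nl)
    ord <- integer(n)
    ord[ok] <- cmap[nl[ok]]
    nbr[, d] <- ord
  }

  # boundary faces: fluid cell with non-fluid (or out-of-domain) neighbour
  bc_cell <- integer(0); bc_dir <- integer(0)
  for (d in 1:6) {
    open <- which(nbr[, d] == 0L)
    bc_cell <- c(bc_cell, open)
    bc_dir <- c(bc_dir, rep.int(d, length(open)))
  }
  centers <- cell_centers_raw(fluid_idx[bc_cell], dims, origin, h)
  fcent <- centers + (h / 2) * DIR_VECS[bc_dir, , drop = FALSE]
  patch <- rep("wall", length(bc_cell))
  if (!is.null(classify) && length(bc_cell)) {
    for (d in 1:6) {
      sel <- bc_dir == d
      if (any(sel)) patch[sel] <- classify(fcent[sel, , drop = FALSE], d)
    }
  }
  # device-surface faces: neighbour cell exists and is device
  if (any(cell_class == CELL_DEVICE) && length(bc_cell)) {
    nl <- nbr_lin[cbind(bc_cell, bc_dir)]
    dev <- !is.na(nl) & cell_class[nl] == CELL_DEVICE
    patch[dev] <- "device_surface"
  }
  bfaces <- data.frame(
    cell = bc_cell, dir = bc_dir, patch = patch,
    bc_type = patch_bc_type(patch), stringsAsFactors = FALSE
  )
  bfaces$area <- rep(h^2, nrow(bfaces))
  # default inflow geometry: flow along the inward face normal
  inl <- bfaces$bc_type == "inlet"
  bfaces$scale <- ifelse(inl, 1, NA_real_)
  nrm <- DIR_VECS[bfaces$dir, , drop = FALSE]
  bfaces$bdir1 <- ifelse(inl, -nrm[, 1], NA_real_)
  bfaces$bdir2 <- ifelse(inl, -nrm[, 2], NA_real_)
  bfaces$bdir3 <- ifelse(inl, -nrm[, 3], NA_real_)

  g <- structure(list(
    dims = dims, h = h, origin = origin, periodic = periodic,
    cell_class = cell_class, fluid_idx = fluid_idx, cmap = cmap,
    nbr = nbr, bfaces = bfaces, cell_volume = h^3,
    n_fluid = n
  ), class = "laa_grid")
  g
}

#' Remove diagonal pinch configurations from a fluid mask
#'
#' Two fluid cells that touch only along a cell edge (their two common
#' face-neighbours both solid) make the voxel surface non-manifold. This
#' fills one of the two missing face-neighbours (deterministically the
#' lexicographically first), iterating until no pinch remains, so the
#' extracted surface satisfies the edge-manifold property.
#'
#' @param mask logical 3d array, `TRUE` = fluid
#' @return repaired mask
#' @export
fix_pinch <- function(mask) {
  d <- dim(mask)
  shift <- function(m, v) {
    # neighbour value at offset v, FALSE outside
    out <- array(FALSE, dim = d)
    xs <- seq_len(d[1]) + v[1]; ys <- seq_len(d[2]) + v[2]; zs <- seq_len(d[3]) + v[3]
    okx <- xs >= 1 & xs <= d[1]; oky <- ys >= 1 & ys <= d[2]; okz <- zs >= 1 & zs <= d[3]
    out[okx, oky, okz] <- m[xs[okx], ys[oky], zs[okz]]
    out
  }
  axpairs <- list(c(1, 2), c(1, 3), c(2, 3))
  for (iter in 1:8) {
    changed <- FALSE
    for (ap in axpairs) {
      e1 <- c(0, 0, 0); e1[ap[1]] <- 1
      e2 <- c(0, 0, 0); e2[ap[2]] <- 1
      for (s in list(c(1, 1), c(1, -1))) {
        v1 <- s[1] * e1; v2 <- s[2] * e2
        diag_f <- shift(mask, v1 + v2)
        n1 <- shift(mask, v1); n2 <- shift(mask, v2)
        pinch <- mask & diag_f & !n1 & !n2
        if (any(pinch)) {
          # fill the face-neighbour in the first axis direction
          idx <- which(pinch)
          i <- (idx - 1) %% d[1] + 1
          j <- ((idx - 1) %/% d[1]) %% d[2] + 1
          k <- (idx - 1) %/% (d[1] * d[2]) + 1
          tgt <- cbind(i, j, k)
          tgt[, ap[1]] <- tgt[, ap[1]] + s[1]
          mask[tgt] <- TRUE
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  mask
}

cell_centers_raw <- function(idx, dims, origin, h) {
  i <- (idx - 1L) %% dims[1]
  j <- ((idx - 1L) %/% dims[1]) %% dims[2]
  k <- (idx - 1L) %/% (dims[1] * dims[2])
  cbind(origin[1] + (i + 0.5) * h, origin[2] + (j + 0.5) * h, origin[3] + (k + 0.5) * h)
}

# map patch labels to solver boundary-condition types
patch_bc_type <- function(patch) {
  bc <- rep("wall", length(patch))
  bc[grepl("^pv_inlet|^inlet", patch)] <- "inlet"
  bc[grepl("^mv_outlet|^outlet", patch)] <- "outlet"
  bc[patch == "symmetry"] <- "symmetry"
  bc[patch == "device_surface"] <- "wall"
  bc
}

#' Total fluid volume of a grid
#' @param grid an `laa_grid`
#' @return volume in mm^3
#' @export
fluid_volume <- function(grid) grid$n_fluid * grid$cell_volume

#' Keep only fluid cells connected to the outlet
#'
#' Breadth-first flood fill over face-connected fluid cells, seeded at the
#' outlet faces. Unreachable pockets (e.g. the appendage sealed behind an
#' occluder) are reclassified solid and the grid rebuilt. If the grid has no
#' outlet faces it is returned unchanged.
#'
#' @param grid an `laa_grid`
#' @param classify patch classifier used to rebuild boundary faces
#' @return list(grid, n_removed)
#' @export
prune_disconnected <- function(grid, classify = NULL) {
  seeds <- unique(grid$bfaces$cell[grid$bfaces$bc_type == "outlet"])
  if (length(seeds) == 0L) return(list(grid = grid, n_removed = 0L))
  visited <- logical(grid$n_fluid)
  visited[seeds] <- TRUE
  frontier <- seeds
  while (length(frontier)) {
    nxt <- unique(as.vector(grid$nbr[frontier, ]))
    nxt <- nxt[nxt > 0L]
    nxt <- nxt[!visited[nxt]]
    visited[nxt] <- TRUE
    frontier <- nxt
  }
  if (all(visited)) return(list(grid = grid, n_removed = 0L))
  removed <- grid$fluid_idx[!visited]
  cls <- grid$cell_class
  cls[removed] <- CELL_SOLID
  g2 <- grid_from_mask(cls == CELL_FLUID, grid$h, grid$origin, grid$periodic,
                       classify = classify, cell_class = cls)
  list(grid = g2, n_removed = length(removed))
}

#' Rectangular benchmark box grid
#'
#' Builds an all-fluid box of `n = c(nx,ny,nz)` cells with boundary patches
#' given per side (`xlo`, `xhi`, `ylo`, `yhi`, `zlo`, `zhi`), each one of
#' `"wall"`, `"inlet"`, `"outlet"`, `"symmetry"` or `"periodic"`. Used by the
#' analytic channel benchmarks and the washout oracle.
#'
#' @param n integer cells per axis
#' @param h cell size (mm)
#' @param sides named list/character of patch per side
#' @return an `laa_grid`
#' @export
make_box_grid <- function(n, h, sides = list()) {
  defaults <- list(xlo = "wall", xhi = "wall", ylo = "wall", yhi = "wall",
                   zlo = "wall", zhi = "wall")
  sides <- utils::modifyList(defaults, as.list(sides))
  periodic <- c(
    identical(sides$xlo, "periodic") || identical(sides$xhi, "periodic"),
    identical(sides$ylo, "periodic") || identical(sides$yhi, "periodic"),
    identical(sides$zlo, "periodic") || identical(sides$zhi, "periodic")
  )
  mask <- array(TRUE, dim = n)
  ext <- n * h
  side_of <- c("xhi", "xlo", "yhi", "ylo", "zhi", "zlo")  # by direction 1..6
  classify <- function(centers, d) rep(sides[[side_of[d]]], nrow(centers))
  grid_from_mask(mask, h, origin = c(0, 0, 0), periodic = periodic, classify = classify)
}

#' @export
print.laa_grid <- function(x, ...) {
  cat("laa_grid: ", paste(x$dims, collapse = " x "), " cells at h = ", x$h, " mm\n", sep = "")
  cat("  fluid cells: ", x$n_fluid, " (", format(fluid_volume(x) / 1000, digits = 4),
      " mL)\n", sep = "")
  tb <- table(x$bfaces$patch)
  cat("  boundary faces:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
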