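# Surrogate markers of device-related thrombus risk.
#
# Per wall/device face over an integration period T (the last cardiac cycle
# by default):
#   TAWSS = (1/T) int |tau_w| dt           (time-averaged wall shear, Pa)
#   OSI   = 0.5 (1 - |int tau_w dt| / int |tau_w| dt)   (in [0, 0.5])
#   ECAP  = OSI / TAWSS                    (1/Pa)
# with the adhesion threshold TAWSS < 0.36 Pa and the activation threshold
# ECAP > 1.4 1/Pa. Volume markers: ROI-averaged speed and vorticity.

#' Time-averaged wall shear stress per face
#'
#' Trapezoidal integration of `|tau_w|` over the stored samples.
#'
#' @param tau array (n_times x n_faces x 3) of wall shear vectors (Pa)
#' @param times sample times (s); at least two
#' @return TAWSS per face (Pa)
#' @export
tawss <- function(tau, times) {
  nt <- length(times)
  if (nt < 2) stop("TAWSS integration undefined for a single sample")
  stopifnot(dim(tau)[1] == nt)
  mag <- sqrt(tau[, , 1]^2 + tau[, , 2]^2 + tau[, , 3]^2)
  if (is.null(dim(mag))) mag <- matrix(mag, nrow = nt)
  trapz_cols(times, mag) / (times[nt] - times[1])
}

# trapezoid rule down the rows for each column
trapz_cols <- function(times, m) {
  nt <- length(times)
  w <- diff(times)
  colSums((m[-nt, , drop = FALSE] + m[-1, , drop = FALSE]) * w / 2)
}

#' Oscillatory shear index per face
#'
#' `OSI = 0.5 (1 - |int tau dt| / int |tau| dt)`, in `[0, 0.5]`. Faces with
#' zero integrated shear magnitude get OSI 0 and are flagged in the
#' `"zero_shear"` attribute.
#'
#' @inheritParams tawss
#' @return OSI per face with attribute `zero_shear` (logical)
#' @export
osi <- function(tau, times) {
  nt <- length(times)
  if (nt < 2) stop("OSI integration undefined for a single sample")
  mag <- sqrt(tau[, , 1]^2 + tau[, , 2]^2 + tau[, , 3]^2)
  if (is.null(dim(mag))) mag <- matrix(mag, nrow = nt)
  denom <- trapz_cols(times, mag)
  vx <- trapz_cols(times, matrix(tau[, , 1], nrow = nt))
  vy <- trapz_cols(times, matrix(tau[, , 2], nrow = nt))
  vz <- trapz_cols(times, matrix(tau[, , 3], nrow = nt))
  num <- sqrt(vx^2 + vy^2 + vz^2)
  zero <- denom <= 0
  out <- numeric(length(denom))
  out[!zero] <- 0.5 * (1 - num[!zero] / denom[!zero])
  out <- pmin(pmax(out, 0), 0.5)
  attr(out, "zero_shear") <- zero
  out
}

#' Endothelial cell activation potential per face, with area statistics
#'
#' `ECAP = OSI / TAWSS`; faces with zero TAWSS are excluded from the
#' area-weighted averages and flagged.
#'
#' @param osi_vals OSI per face
#' @param tawss_vals TAWSS per face (Pa)
#' @param areas face areas (any consistent unit); default equal weights
#' @param threshold activation threshold (1/Pa)
#' @return list: `ecap` per face (`NA` where TAWSS = 0), `mean_ecap`
#'   (area-weighted), `frac_area_high` (area fraction with ECAP > threshold),
#'   `excluded` (logical)
#' @export
ecap <- function(osi_vals, tawss_vals, areas = rep(1, length(osi_vals)),
                 threshold = 1.4) {
  stopifnot(length(osi_vals) == length(tawss_vals))
  ex <- tawss_vals <= 0
  e <- ifelse(ex, NA_real_, as.numeric(osi_vals) / tawss_vals)
  ok <- !ex
  mean_e <- if (any(ok)) sum(e[ok] * areas[ok]) / sum(areas[ok]) else NA_real_
  frac_hi <- if (any(ok)) sum(areas[ok][e[ok] > threshold]) / sum(areas) else NA_real_
  list(ecap = e, mean_ecap = mean_e, frac_area_high = frac_hi, excluded = ex,
       threshold = threshold)
}

#' Area fraction of critically low wall shear
#'
#' Fraction (by area) of faces with TAWSS below the platelet-adhesion
#' threshold of 0.36 Pa.
#'
#' @param tawss_vals TAWSS per face (Pa)
#' @param areas face areas; default equal
#' @param threshold Pa
#' @return fraction in `[0, 1]`
#' @export
low_wss_area <- function(tawss_vals, areas = rep(1, length(tawss_vals)),
                         threshold = 0.36) {
  sum(areas[tawss_vals < threshold]) / sum(areas)
}

#' Faces forming the ROI surface
#'
#' Wall and device faces whose centroid lies inside the ROI sphere and that
#' are not adjacent to cells excluded as distal to the device.
#'
#' @param grid an `laa_grid`
#' @param roi ROI from [build_roi()]
#' @param device_only / `tissue_only` restrict to device or tissue faces
#' @return integer rows into `grid$bfaces`
#' @export
roi_surface_faces <- function(grid, roi, device_only = FALSE, tissue_only = FALSE) {
  bf <- grid$bfaces
  rows <- which(bf$bc_type == "wall")
  if (device_only) rows <- rows[bf$patch[rows] == "device_surface"]
  if (tissue_only) rows <- rows[bf$patch[rows] != "device_surface"]
  ctr <- cell_centers(grid, grid$fluid_idx[bf$cell[rows]])
  fc <- ctr + (grid$h / 2) * DIR_VECS[bf$dir[rows], , drop = FALSE]
  inside <- rowSums(sweep(fc, 2, roi$center)^2) <= (roi$diameter / 2)^2
  notdist <- !roi$excluded[bf$cell[rows]]
  rows[inside & notdist]
}

#' Discrete curl of a cell-centred velocity field
#'
#' Centred differences on fluid cells, falling back to one-sided differences
#' where a neighbour is missing (treating the wall side as no contribution).
#'
#' @param u n x 3 velocities (m/s)
#' @param grid an `laa_grid`
#' @return n x 3 vorticity vectors (1/s)
#' @export
curl_field <- function(u, grid) {
  hm <- grid$h / 1000
  nbr <- grid$nbr
  grad <- function(comp, axis) {
    dplus <- c(1L, 3L, 5L)[axis]; dminus <- dplus + 1L
    jp <- nbr[, dplus]; jm <- nbr[, dminus]
    hasp <- jp > 0L; hasm <- jm > 0L
    up <- ifelse(hasp, u[ifelse(hasp, jp, 1L), comp], u[, comp])
    um <- ifelse(hasm, u[ifelse(hasm, jm, 1L), comp], u[, comp])
    span <- (as.numeric(hasp) + as.numeric(hasm)) * hm
    out <- numeric(nrow(nbr))
    ok <- span > 0
    out[ok] <- (up[ok] - um[ok]) / span[ok]
    out
  }
  wx <- grad(3, 2) - grad(2, 3)
  wy <- grad(1, 3) - grad(3, 1)
  wz <- grad(2, 1) - grad(1, 2)
  cbind(wx, wy, wz)
}

#' ROI flow statistics over stored samples
#'
#' Time average over the stored window of the ROI volume average of the
#' speed and of the vorticity magnitude. The vorticity is reported both as a
#' volume average (1/s) and as a volume integral (m^3/s), since both
#' conventions are in use.
#'
#' @param u_series list of n x 3 velocity matrices (m/s)
#' @param times sample times (s)
#' @param grid an `laa_grid`
#' @param roi_mask logical over fluid cells
#' @return list: `avg_velocity` (m/s), `avg_vorticity` (1/s),
#'   `integral_vorticity` (m^3/s)
#' @export
roi_flow_stats <- function(u_series, times, grid, roi_mask) {
  if (!length(u_series)) stop("no stored samples for the evaluation window")
  vol_m3 <- grid$cell_volume * 1e-9
  sel <- which(roi_mask)
  speeds <- vapply(u_series, function(u)
    mean(sqrt(rowSums(u[sel, , drop = FALSE]^2))), numeric(1))
  vor_avg <- numeric(length(u_series))
  vor_int <- numeric(length(u_series))
  for (i in seq_along(u_series)) {
    w <- curl_field(u_series[[i]], grid)
    wm <- sqrt(rowSums(w[sel, , drop = FALSE]^2))
    vor_avg[i] <- mean(wm)
    vor_int[i] <- sum(wm) * vol_m3
  }
  list(avg_velocity = mean(speeds), avg_vorticity = mean(vor_avg),
       integral_vorticity = mean(vor_int))
}

#' Assemble the per-scenario marker report row
#'
#' One row with the summary-table column set: ROI-averaged velocity and
#' vorticity, washout half-time, residual-blood fraction, averaged wall
#' shear and ECAP, threshold-exceedance area fractions, and the device
#' position metrics (nulls pre-occlusion).
#'
#' @param scenario_id character label
#' @param flow_stats from [roi_flow_stats()]
#' @param wash `washout_halftime` object
#' @param phi_final residual fraction at the end of the evaluation window
#' @param tawss_vals,osi_vals per ROI-surface face
#' @param areas face areas
#' @param position `laa_position_metrics` or `NULL`
#' @param complete logical: all stages ran
#' @return one-row data.frame
#' @export
build_report <- function(scenario_id, flow_stats, wash, phi_final,
                         tawss_vals, osi_vals, areas, position = NULL,
                         complete = TRUE) {
  ec <- ecap(osi_vals, tawss_vals, areas)
  aw <- sum(tawss_vals * areas) / sum(areas)
  data.frame(
    scenario = scenario_id,
    avg_velocity = flow_stats$avg_velocity,
    avg_vorticity = flow_stats$avg_vorticity,
    integral_vorticity = flow_stats$integral_vorticity,
    washout_half_time = if (wash$censored) NA_real_ else wash$t_half,
    halftime_censored = wash$censored,
    phi_final = phi_final,
    avg_wss = aw,
    avg_ecap = ec$mean_ecap,
    frac_area_low_wss = low_wss_area(tawss_vals, areas),
    frac_area_high_ecap = ec$frac_area_high,
    lupv_ridge_length = if (is.null(position)) NA_real_ else position$lupv_ridge_length,
    implant_depth_mv = if (is.null(position)) NA_real_ else position$implant_depth_mv,
    device_ridge_angle = if (is.null(position)) NA_real_ else position$device_ridge_angle,
    compression_rate = if (is.null(position)) NA_real_ else position$compression_rate,
    deep_flag = if (is.null(position)) NA else position$deep_flag,
    complete = complete,
    stringsAsFactors = FALSE
  )
}
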