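# Passive "old blood" tracer transport and washout quantification.
#
# The tracer marks blood present at the start of the evaluation window
# (c = 1 everywhere); fresh blood enters at c = 0 through the pulmonary
# veins. Transport is conservative finite-volume advection on the solver's
# divergence-free face fluxes, second-order upwind with a minmod limiter
# (monotone), with automatic sub-stepping to keep the advective CFL <= 0.45.
# There is no molecular diffusion term; numerical diffusion is bounded by
# the limiter.

minmod <- function(a, b) {
  s <- sign(a)
  ifelse(s * sign(b) > 0, s * pmin(abs(a), abs(b)), 0)
}

#' Advect the tracer field one step
#'
#' @param c tracer concentration per fluid cell (1 = old blood)
#' @param ops flow operators from [build_flow_ops()]
#' @param Uf interior face normal velocities (from a flow state)
#' @param bU boundary-face outward normal velocities (from a flow state)
#' @param dt time step (s)
#' @param inlet_c concentration carried by inflow (default 0 = fresh blood)
#' @return updated concentration vector
#' @export
advect_tracer <- function(c, ops, Uf, bU, dt, inlet_c = 0) {
  hm <- ops$hm
  umax <- max(vapply(Uf, function(x) if (length(x)) max(abs(x)) else 0, numeric(1)),
              max(abs(bU)), 1e-15)
  nsub <- max(1L, ceiling(umax * dt / (0.45 * hm)))
  dts <- dt / nsub
  nbr <- ops$grid$nbr
  bf <- ops$bf
  for (s in seq_len(nsub)) {
    dc <- numeric(ops$n)
    for (k in 1:3) {
      ax <- c("x", "y", "z")[k]
      fp <- ops$fpairs[[ax]]
      if (!length(fp$i)) next
      U <- Uf[[ax]]
      pos <- U > 0
      donor <- ifelse(pos, fp$i, fp$j)
      accep <- ifelse(pos, fp$j, fp$i)
      dminus <- c(2L, 4L, 6L)[k]; dplus <- c(1L, 3L, 5L)[k]
      upup <- ifelse(pos, nbr[cbind(fp$i, dminus)], nbr[cbind(fp$j, dplus)])
      cd <- c[donor]; ca <- c[accep]
      corr <- numeric(length(U))
      hasuu <- upup > 0L
      corr[hasuu] <- 0.5 * minmod(ca[hasuu] - cd[hasuu], cd[hasuu] - c[upup[hasuu]])
      cf <- cd + corr
      fl <- U * cf
      dc[fp$i] <- dc[fp$i] - fl
      dc[fp$j] <- dc[fp$j] + fl
    }
    for (g in ops$bgroups) {
      cells <- bf$cell[g]
      bu <- bU[g]
      # outflow carries the cell value; inflow carries inlet_c at inlets and
      # the cell value (zero gradient) at outlet backflow
      cin <- ifelse(bf$bc_type[g] == "inlet", inlet_c, c[cells])
      cface <- ifelse(bu > 0, c[cells], cin)
      dc[cells] <- dc[cells] - bu * cface
    }
    c <- c + dts * dc / hm
  }
  c
}

#' Residual-blood fraction in a region of interest
#'
#' The concentration-weighted volume fraction
#' `phi = sum(c V) / sum(V)` over the ROI cells. A binary variant
#' (`threshold`) counts cells with `c >= threshold` instead.
#'
#' @param c tracer concentration per fluid cell
#' @param roi_mask logical mask over fluid cells
#' @param cell_volume scalar or per-cell volumes
#' @param threshold optional binary cut (e.g. 0.5); default `NULL` = weighted
#' @return phi in `[0, 1]`
#' @export
residual_fraction <- function(c, roi_mask, cell_volume = 1, threshold = NULL) {
  if (!any(roi_mask)) stop("empty ROI")
  v <- if (length(cell_volume) == 1L) rep(cell_volume, length(c)) else cell_volume
  w <- if (is.null(threshold)) c[roi_mask] else as.numeric(c[roi_mask] >= threshold)
  sum(w * v[roi_mask]) / sum(v[roi_mask])
}

#' Washout half-time from a phi(t) curve
#'
#' First crossing of phi = 0.5, located by linear interpolation between
#' samples. If phi never reaches 0.5 within the window the half-time is
#' censored (`NA` with `censored = TRUE`). A non-monotone curve that
#' re-crosses 0.5 keeps the first crossing and sets `multi_crossing`.
#'
#' @param times sample times (s), from the start of the evaluation window
#' @param phi residual fractions at `times`
#' @return object of class `washout_halftime`: list(t_half, censored,
#'   multi_crossing)
#' @export
washout_halftime <- function(times, phi) {
  stopifnot(length(times) == length(phi), length(phi) >= 2)
  below <- phi < 0.5
  if (!any(below)) {
    return(structure(list(t_half = NA_real_, censored = TRUE,
                          multi_crossing = FALSE), class = "washout_halftime"))
  }
  i <- which(below)[1]
  if (i == 1L) {
    th <- times[1]
  } else {
    f <- (phi[i - 1] - 0.5) / (phi[i - 1] - phi[i])
    th <- times[i - 1] + f * (times[i] - times[i - 1])
  }
  multi <- any(phi[i:length(phi)] > 0.5)
  structure(list(t_half = th, censored = FALSE, multi_crossing = multi),
            class = "washout_halftime")
}

#' @export
print.washout_halftime <- function(x, ...) {
  if (x$censored) cat("washout half-time: censored (phi never reached 0.5)\n")
  else cat(sprintf("washout half-time: %.3f s%s\n", x$t_half,
                   if (x$multi_crossing) " (non-monotone curve; first crossing)" else ""))
  invisible(x)
}
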