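# Marker kernels: TAWSS, OSI, ECAP, threshold areas, vorticity statistics.

# build a (nt x nf x 3) shear series from a function of time per face
shear_series <- function(times, fns) {
  nf <- length(fns)
  tau <- array(0, c(length(times), nf, 3))
  for (j in seq_len(nf)) tau[, j, ] <- t(vapply(times, fns[[j]], numeric(3)))
  tau
}

test_that("TAWSS: constants, sinusoid closed form, refined-quadrature check", {
  t <- seq(0, 1, length.out = 201)
  tau <- shear_series(t, list(function(ti) c(0.3, 0, 0)))
  expect_equal(unname(tawss(tau, t)), 0.3, tolerance = 1e-12)
  # |A sin| integrates to 2A/pi per period
  A <- 0.8
  tau2 <- shear_series(t, list(function(ti) c(A * sin(2 * pi * ti), 0, 0)))
  expect_equal(unname(tawss(tau2, t)), 2 * A / pi, tolerance = 0.005 * 2 * A / pi)
  # sampled arbitrary series matches a 10x-refined trapezoid quadrature
  f <- function(ti) c(0.2 + 0.1 * sin(2 * pi * ti), 0.05 * cos(4 * pi * ti), 0)
  tfine <- seq(0, 1, length.out = 2001)
  ref <- tawss(shear_series(tfine, list(f)), tfine)
  got <- tawss(shear_series(t, list(f)), t)
  expect_equal(unname(got), unname(ref), tolerance = 0.005)
  expect_error(tawss(array(1, c(1, 1, 3)), 0), "single sample")
})

test_that("OSI: steady zero, reversing half, printed-series hand check", {
  t <- seq(0, 1, length.out = 401)
  steady <- shear_series(t, list(function(ti) c(0.25, 0.1, 0)))
  expect_equal(as.numeric(osi(steady, t)), 0, tolerance = 1e-12)
  # zero-mean perfect reversal -> 0.5
  rev <- shear_series(t, list(function(ti) c(sin(2 * pi * ti), 0, 0)))
  expect_equal(as.numeric(osi(rev, t)), 0.5, tolerance = 0.01)
  # +2A for half the period, -A for the other half: hand-computed ratio
  A <- 0.3
  sq <- shear_series(t, list(function(ti) c(if (ti %% 1 < 0.5) 2 * A else -A, 0, 0)))
  # |int| = (2A - A)/2 = A/2; int|.| = (2A + A)/2 = 3A/2; OSI = 0.5(1 - 1/3)
  expect_equal(as.numeric(osi(sq, t)), 0.5 * (1 - 1 / 3), tolerance = 0.01)
  # zero-shear face flagged, OSI 0
  z <- shear_series(t, list(function(ti) c(0, 0, 0)))
  oz <- osi(z, t)
  expect_equal(as.numeric(oz), 0)
  expect_true(attr(oz, "zero_shear"))
})

test_that("OSI stays in [0, 0.5] on random series (triangle inequality)", {
  set.seed(7)
  t <- seq(0, 1, length.out = 101)
  tau <- array(rnorm(101 * 40 * 3), c(101, 40, 3))
  o <- osi(tau, t)
  expect_true(all(o >= 0 & o <= 0.5))
})

test_that("ECAP arithmetic, identity on random maps, exclusions", {
  expect_equal(ecap(0.25, 0.5)$ecap, 0.5)
  expect_equal(ecap(0, 0.7)$ecap, 0)
  set.seed(11)
  o <- runif(50, 0, 0.5)
  tw <- runif(50, 0.05, 1)
  e <- ecap(o, tw)
  expect_equal(e$ecap * tw, o, tolerance = 1e-12)   # ECAP * TAWSS = OSI
  # zero-TAWSS faces excluded from averages
  tw[3] <- 0
  e2 <- ecap(o, tw, areas = rep(1, 50))
  expect_true(e2$excluded[3])
  expect_true(is.na(e2$ecap[3]))
  expect_equal(e2$mean_ecap, mean((o / tw)[-3]), tolerance = 1e-12)
})

test_that("area-weighted ECAP mean and exceedance match a hand-worked map", {
  # four faces with tabulated areas and values
  o <- c(0.4, 0.1, 0.3, 0.05)
  tw <- c(0.2, 0.5, 0.1, 0.4)
  ar <- c(1, 2, 3, 4)
  e <- ecap(o, tw, ar)
  vals <- o / tw          # 2.0, 0.2, 3.0, 0.125
  expect_equal(e$mean_ecap, sum(vals * ar) / sum(ar), tolerance = 1e-12)
  expect_equal(e$frac_area_high, (1 + 3) / 10, tolerance = 1e-12)  # > 1.4
})

test_that("low-WSS area fraction: all-high zero, all-low one, mixed brute force", {
  expect_equal(low_wss_area(rep(0.5, 7)), 0)
  expect_equal(low_wss_area(rep(0.1, 7)), 1)
  set.seed(3)
  tw <- runif(30, 0, 1)
  ar <- runif(30, 0.5, 2)
  expect_equal(low_wss_area(tw, ar), sum(ar[tw < 0.36]) / sum(ar),
               tolerance = 1e-12)
})

test_that("vorticity: linear shear exact, uniform translation zero", {
  g <- make_box_grid(c(6, 6, 4), 1)
  ctr <- cell_centers(g) / 1000
  gamma <- 30
  u <- cbind(gamma * ctr[, 2], 0, 0)
  w <- curl_field(u, g)
  # omega = (0, 0, -gamma) for u = (gamma y, 0, 0)
  interior <- rowSums(g$nbr > 0) == 6
  expect_equal(unname(w[interior, 3]), rep(-gamma, sum(interior)), tolerance = 1e-9)
  expect_equal(max(abs(w[interior, 1:2])), 0, tolerance = 1e-12)
  wu <- curl_field(matrix(0.2, g$n_fluid, 3), g)
  expect_equal(max(abs(wu)), 0, tolerance = 1e-12)
})

test_that("smooth-field curl matches a refined-grid evaluation", {
  field <- function(p) cbind(sin(300 * p[, 3]), cos(250 * p[, 1]), sin(200 * p[, 2]))
  curl_exact <- function(p) cbind(200 * cos(200 * p[, 2]) - 0,
                                  300 * cos(300 * p[, 3]) - 0,
                                  -250 * sin(250 * p[, 1]))
  g <- make_box_grid(c(10, 10, 10), 1)
  p <- cell_centers(g) / 1000
  w <- curl_field(field(p), g)
  interior <- rowSums(g$nbr > 0) == 6
  err <- max(abs(w[interior, ] - curl_exact(p)[interior, ]))
  scale <- max(abs(curl_exact(p)))
  expect_lt(err / scale, 0.02)   # second-order centred differences at h = 1 mm
})

test_that("steady flow degenerates to OSI and ECAP identically zero", {
  t <- seq(0, 1, length.out = 51)
  tau <- shear_series(t, replicate(5, function(ti) c(0.3, 0.2, 0.1), simplify = FALSE))
  o <- osi(tau, t)
  expect_equal(max(abs(o)), 0, tolerance = 1e-12)
  e <- ecap(o, tawss(tau, t))
  expect_equal(max(abs(e$ecap)), 0, tolerance = 1e-12)
})

test_that("report assembly carries units, nulls and completeness flags", {
  t <- seq(0, 1, length.out = 51)
  tau <- shear_series(t, list(function(ti) c(0.3 * sin(2 * pi * ti), 0, 0),
                              function(ti) c(0.5, 0, 0)))
  tw <- tawss(tau, t); o <- osi(tau, t)
  stats <- list(avg_velocity = 0.05, avg_vorticity = 12, integral_vorticity = 3e-4)
  wash <- washout_halftime(c(0, 0.5, 1), c(1, 0.6, 0.3))
  row <- build_report("toy", stats, wash, 0.3, tw, o, areas = c(1, 1))
  expect_equal(nrow(row), 1)
  expect_true(is.na(row$lupv_ridge_length))   # pre-occlusion: null metrics
  expect_true(row$complete)
  expect_gte(row$frac_area_low_wss, 0); expect_lte(row$frac_area_low_wss, 1)
})
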