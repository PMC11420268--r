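# Device models, deployment, seal property and position metrics.

test_that("compression rate reproduces the sizing arithmetic", {
  # 24 mm plug into a 21.4 mm lumen -> about 11 % compression
  expect_equal(1 - 21.4 / 24, 0.1083, tolerance = 1e-3)
  a <- default_anatomy()
  g <- default_grid()
  dep <- deploy(g, laao_device("non_pacifier", 27), laa_placement(0))
  expect_gt(dep$compression_rate, 0.08)
  expect_lt(dep$compression_rate, 0.20)
  expect_equal(dep$compression_rate, 0.110, tolerance = 0.01)
})

test_that("a device matching the lumen exactly triggers the release warning", {
  a <- default_anatomy()
  g <- default_grid()
  lumen <- 2 * laa_lumen_radius(a, 11.5)  # mid-body depth of an ostial plug
  dev <- laao_device("non_pacifier", 0, deployed_diameter = lumen,
                     body_length = 23)
  expect_warning(deploy(g, dev, laa_placement(0)),
                 class = "laaoflow_release_warning")
})

test_that("deployed device volume matches the analytic solid on a fine grid", {
  # deploy into a large empty box so no wall accommodation interferes
  a <- default_anatomy()
  dev <- laao_device("non_pacifier", 27)
  pose <- list(anchor = c(0, 0, 0), axis = c(0, 0, 1))
  h <- 0.5
  n <- 61
  xs <- (seq_len(n) - (n + 1) / 2) * h
  p <- as.matrix(expand.grid(xs, xs, seq(-5, 28, by = h)))
  inside <- laaoflow:::device_inside(dev, pose, p)
  v_vox <- sum(inside) * h^3
  # oracle: cylinder minus shoulder ring (1d quadrature of the solid of
  # revolution) minus the cove recess
  R <- dev$deployed_diameter / 2; L <- dev$body_length; s <- dev$shoulder_radius
  v_cyl <- pi * R^2 * L
  rmax <- function(z) R - s + sqrt(pmax(s^2 - (s - z)^2, 0))
  v_shoulder <- stats::integrate(function(z) pi * (R^2 - rmax(z)^2), 0, s,
                                 rel.tol = 1e-10)$value
  v_cove <- pi * dev$cove_radius^2 * dev$cove_depth
  v_exact <- v_cyl - v_shoulder - v_cove
  expect_lt(abs(v_vox - v_exact) / v_exact, 0.02)
})

test_that("ostial plug seals the appendage; tilted placement leaks", {
  g <- default_grid()
  dev <- laao_device("non_pacifier", 27)
  dep <- deploy(g, dev, laa_placement(0))
  expect_true(dep$sealed)
  # flood-fill check: no fluid cell distal to the device survives pruning
  expect_false(laaoflow:::any_distal_fluid(dep$grid, dev, dep$pose))
  tl <- laa_placement(depth_offset = 2, tilt = -13.6, tilt_toward = "lupv",
                      lateral_offset = 4, lateral_toward = "mv")
  dep_tl <- suppressWarnings(deploy(g, dev, tl))
  expect_false(dep_tl$sealed)
})

test_that("position metrics are exact on constructed placements", {
  a <- default_anatomy()
  dev <- laao_device("non_pacifier", 27)
  # ostium-fitted: ridge about 0, not deep
  m0 <- measure_position(a, dev, laa_placement(0))
  expect_equal(m0$lupv_ridge_length, 0)
  expect_false(m0$deep_flag)
  expect_equal(m0$device_ridge_angle, 180)
  # proximal: ridge 0 with proximal flag
  mp <- measure_position(a, dev, laa_placement(-5))
  expect_equal(mp$lupv_ridge_length, 0)
  expect_true(mp$proximal_flag)
  # tilt 14 deg in the measurement plane -> alpha = 166 within 1 deg
  mt <- measure_position(a, dev, laa_placement(2, tilt = -14, tilt_toward = "lupv"))
  expect_equal(mt$device_ridge_angle, 166, tolerance = 1)
  # deep target inversions recover the target ridge lengths
  for (target in c(27, 15.5, 10.1)) {
    md <- measure_position(a, dev, laa_placement(depth_for_ridge(a, target)))
    expect_equal(md$lupv_ridge_length, target, tolerance = 1e-6)
    expect_equal(md$deep_flag, target > 10)
  }
})

test_that("deep flag follows the 10 mm rule exactly at the boundary", {
  a <- default_anatomy()
  dev <- laao_device("non_pacifier", 24)
  just_below <- measure_position(a, dev, laa_placement(depth_for_ridge(a, 9.99)))
  just_above <- measure_position(a, dev, laa_placement(depth_for_ridge(a, 10.01)))
  expect_false(just_below$deep_flag)
  expect_true(just_above$deep_flag)
})

test_that("the scenario suite matches the study design", {
  suite <- scenario_suite()
  expect_length(suite, 9)
  expect_named(suite, c("pre_laao", "np_cl", "np_os", "np_tl", "np_ds",
                        "lp_os", "lp_ds", "sp_os", "sp_ds"))
  expect_null(suite$pre_laao$device)
  # deep plug implantation uses the smaller plug
  expect_equal(suite$np_ds$device$nominal_size, 24)
  expect_equal(suite$np_os$device$nominal_size, 27)
  # disc sizes: large 32 mm, small 28 mm
  expect_equal(suite$lp_os$device$deployed_diameter, 32)
  expect_equal(suite$sp_os$device$deployed_diameter, 28)
  # encoded ridge-length goals
  a <- suite$np_ds$anatomy
  m <- measure_position(a, suite$sp_ds$device, suite$sp_ds$placement)
  expect_equal(m$lupv_ridge_length, 15.5, tolerance = 1e-6)
  m <- measure_position(a, suite$lp_ds$device, suite$lp_ds$placement)
  expect_equal(m$lupv_ridge_length, 10.1, tolerance = 1e-6)
})
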