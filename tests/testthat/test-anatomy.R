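# Parametric anatomy: construction, patches, volumes, ROI.

test_that("default anatomy yields six labelled patch groups", {
  g <- default_grid()
  patches <- unique(g$bfaces$patch)
  expect_setequal(patches, c("wall", paste0("pv_inlet_", 1:4), "mv_outlet"))
  # labelling completeness: every pulmonary vein exposes inlet faces
  for (i in 1:4) expect_gt(sum(g$bfaces$patch == paste0("pv_inlet_", i)), 0)
})

test_that("degenerate and intersecting configurations are rejected", {
  expect_error(laa_anatomy(laa_depth = 0), "positive")
  expect_error(laa_anatomy(laa_ostium_diameter = 60), "chamber")
  # LUPV aimed straight down the appendage axis must intersect it
  bad_dirs <- rbind(lupv = c(0.90, -0.12, 0.42), llpv = c(0.60, 0.62, -0.50),
                    rupv = c(-0.62, 0.42, 0.66), rlpv = c(-0.70, 0.55, -0.45))
  expect_error(laa_anatomy(pv_dirs = bad_dirs), "intersect")
})

test_that("enclosed volume matches an overlap-corrected voxel oracle within 5%", {
  a <- default_anatomy()
  s <- build_anatomy_surface(a, h = 2.5)
  v_surface <- surface_volume(s)
  # independent oracle: brute-force voxel count of the implicit union on a
  # finer grid, written without the package's grid machinery
  h <- 1
  bb <- laaoflow:::anatomy_bbox(a, 2)
  xs <- seq(bb$lo[1] + h / 2, bb$hi[1], by = h)
  ys <- seq(bb$lo[2] + h / 2, bb$hi[2], by = h)
  zs <- seq(bb$lo[3] + h / 2, bb$hi[3], by = h)
  count <- 0
  for (z in zs) {
    p <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)), z)
    count <- count + sum(anatomy_sdf(a, p) < 0)
  }
  v_oracle <- count * h^3
  expect_lt(abs(v_surface - v_oracle) / v_oracle, 0.05)
})

test_that("anatomy surface is watertight and consistently oriented", {
  s <- build_anatomy_surface(default_anatomy(), h = 2.5)
  wt <- check_watertight(s)
  expect_true(wt$watertight)
  # outward orientation: enclosed volume must be positive
  expect_gt(surface_volume(s), 0)
})

test_that("grid volume is stable under 2x refinement", {
  v1 <- fluid_volume(default_grid(2.5))
  v2 <- fluid_volume(default_grid(1.25))
  expect_lt(abs(v2 - v1) / v2, 0.02)
})

test_that("too-coarse resolution raises a resolution error", {
  expect_error(discretize_anatomy(default_anatomy(), h = 9), "resolution")
})

test_that("ROI mask equals the brute-force sphere test and is deterministic", {
  g <- default_grid()
  roi <- build_roi(g)
  ctr <- cell_centers(g)
  brute <- rowSums(sweep(ctr, 2, roi$center)^2) <= 20^2
  expect_identical(roi$mask, brute)
  expect_equal(roi$volume, sum(brute) * g$cell_volume)
  roi2 <- build_roi(g)
  expect_identical(roi$mask, roi2$mask)
})

test_that("device exclusion shrinks the ROI", {
  g <- default_grid()
  dev <- laao_device("non_pacifier", 27)
  pl <- laa_placement(depth_offset = 0)
  dep <- suppressWarnings(deploy(g, dev, pl))
  roi_pre <- build_roi(g)
  roi_post <- build_roi(dep$grid, dev, pl)
  expect_lt(roi_post$volume, roi_pre$volume)
})

test_that("STL round trip and voxelization recover a cube", {
  g <- make_box_grid(c(4, 4, 4), 2)
  s <- build_surface(g)
  tmp <- tempfile(fileext = ".stl")
  write_stl(s, tmp)
  stl <- read_stl(tmp)
  expect_equal(nrow(stl$triangles), 2 * nrow(s$quads))
  g2 <- voxelize_stl(stl, h = 1)
  expect_lt(abs(fluid_volume(g2) - fluid_volume(g)) / fluid_volume(g), 0.05)
  unlink(tmp)
})
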