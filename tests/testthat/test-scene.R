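test_that("a zero-target wall contains gluten only", {
  p <- simulation_params(target_starch_fraction = 0)
  sc <- build_scene(p, wall_geometry("string", length_um = 16, width_um = 8,
                                     depth_um = 8),
                    canvas_px = c(96, 96), n_slices = 30)
  expect_identical(nrow(sc$granules), 0L)
  expect_true(all(sc$truth_labels == 0L))
  expect_equal(sc$achieved_fraction, 0)
  expect_gt(sum(sc$wall), 0)
})

test_that("achieved fraction hits the target and is recorded exactly", {
  p <- simulation_params(target_starch_fraction = 0.55, seed = 21)
  sc <- build_scene(p, wall_geometry("string", length_um = 20, width_um = 11,
                                     depth_um = 10),
                    canvas_px = c(160, 160), n_slices = 40)
  expect_gte(sc$achieved_fraction, 0.53)
  expect_lte(sc$achieved_fraction, 0.57)
  # recorded value matches a direct voxel recount to 1e-9 relative
  num <- sum(vapply(sc$band, function(k) sum(sc$truth_labels[, , k] > 0),
                    numeric(1)))
  den <- sum(vapply(sc$band, function(k)
    sum(sc$truth_labels[, , k] > 0 | sc$wall[, , k]), numeric(1)))
  expect_equal(sc$achieved_fraction, num / den, tolerance = 1e-9)
})

test_that("granule overlaps stay below 1% of granule voxels", {
  sc <- bulk_scene()
  vol_sum <- 0
  px <- sc$geometry$pixel_size_xy; dz <- sc$geometry$z_step
  for (i in seq_len(nrow(sc$granules))) {
    g <- gcwmorph:::ellipsoid_grid(
      sc$granules$x_um[i], sc$granules$y_um[i], sc$granules$z_um[i],
      sc$granules$a_um[i], sc$granules$b_um[i], sc$granules$c_um[i],
      sc$granules$orientation_rad[i], sc$dims, px, dz)
    vox <- gcwmorph:::rasterize_ellipsoid(g, sc$dims, sc$granules$c_um[i])
    vol_sum <- vol_sum + length(vox$idx)
  }
  actual <- sum(sc$truth_labels > 0)
  expect_lt((vol_sum - actual) / vol_sum, 0.01)
})

test_that("unreachable targets raise a placement error", {
  p <- simulation_params(target_starch_fraction = 0.85)
  expect_error(build_scene(p, wall_geometry("string"), canvas_px = c(64, 64),
                           n_slices = 40),
               class = "gcwmorph_placement_error")
})

test_that("wall geometry invariants are enforced against the stack", {
  # string deeper than 0.6 x stack
  expect_error(build_scene(simulation_params(),
                           wall_geometry("string", depth_um = 9, width_um = 9),
                           canvas_px = c(64, 64), n_slices = 24),
               class = "gcwmorph_parameter_error")
  # intact shallower than 0.9 x stack
  expect_error(build_scene(simulation_params(),
                           wall_geometry("intact", depth_um = 12),
                           canvas_px = c(64, 64), n_slices = 40),
               class = "gcwmorph_parameter_error")
})
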