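test_that("fusing a single SHG channel reproduces it up to rescale", {
  sim <- small_string_sim()
  one <- sim$stack
  keep <- c("SHG_B_045", "EF")
  one$voxels <- one$voxels[keep]
  one$channels <- one$channels[keep]
  comb <- combine_polarizations(one)
  expect_equal(as.vector(comb), as.vector(one$voxels$SHG_B_045),
               tolerance = 1e-12)
})

test_that("sum and max fusion agree on which voxels are zero", {
  sim <- small_string_sim()
  cs <- combine_polarizations(sim$stack, "sum")
  cm <- combine_polarizations(sim$stack, "max")
  expect_identical(cs == 0, cm == 0)
})

test_that("fusion requires at least one SHG channel", {
  sim <- small_string_sim()
  ef_only <- sim$stack
  ef_only$voxels <- ef_only$voxels["EF"]
  ef_only$channels <- ef_only$channels["EF"]
  expect_error(combine_polarizations(ef_only), class = "gcwmorph_input_error")
})

test_that("analyzable depth recovers the analytic exponential cutoff", {
  nz <- 40L; dz <- 0.5
  for (lambda in c(3, 4, 6)) {
    field <- array(0, dim = c(8, 8, nz))
    for (k in seq_len(nz)) field[, , k] <- exp(-((k - 0.5) * dz) / lambda)
    r <- determine_analyzable_depth(field, contrast_floor = 0.1,
                                    geometry = voxel_geometry(z_step = dz))
    expect_lte(abs(r$depth_um - lambda * log(10)), dz)
  }
})

test_that("no attenuation means the full stack is analyzable; empty is flagged", {
  field <- array(1, dim = c(6, 6, 12))
  r <- determine_analyzable_depth(field)
  expect_identical(c(r$z_start, r$z_end), c(1L, 12L))
  r0 <- determine_analyzable_depth(array(0, dim = c(6, 6, 12)))
  expect_true(r0$empty)
  expect_identical(r0$n_slices, 0L)
  expect_error(determine_analyzable_depth(field, contrast_floor = 1.2))
})

test_that("SHG analyzable depth is shorter than EF on default scenes", {
  for (q in list(string_quant(), intact_quant())) {
    expect_lt(q$shg_range$depth_um, q$ef_range$depth_um)
  }
})

test_that("recovered lobe orientation tracks the polarization angle", {
  sc <- NULL
  # granule rendered at each polarization; recovered orientation within 5 deg
  params <- simulation_params(target_starch_fraction = 0, seed = 2)
  sc <- build_scene(params, wall_geometry("bulk", length_um = 18,
                                          width_um = 18, depth_um = 12),
                    canvas_px = c(128, 128), n_slices = 24)
  a <- 4
  sc$granules <- tibble::tibble(
    id = 1L, true_diameter_um = 2 * a, a_um = a, b_um = a, c_um = a,
    orientation_rad = 0, size_class = "B",
    x_um = 128 * 0.17 / 2, y_um = 128 * 0.17 / 2, z_um = 6)
  k <- round(6 / 0.5 + 0.5)
  mask <- matrix(FALSE, 128, 128)
  ctr <- round(128 / 2)
  mask[(ctr - 30):(ctr + 30), (ctr - 30):(ctr + 30)] <- TRUE
  angs <- c(0, 45, 90, 135)
  rec <- vapply(angs, function(ang) {
    f <- render_shg_channel(sc, channel_spec("SHG", "backward", ang))
    compute_anisotropy_orientation(f[, , k], mask)$angle_deg
  }, numeric(1))
  for (i in seq_along(angs)) {
    diff <- min(abs(rec[i] - angs[i]), 180 - abs(rec[i] - angs[i]))
    expect_lte(diff, 5)
  }
  # equivariance: rotating the polarization by 90 deg rotates the recovery
  d01 <- (rec[3] - rec[1]) %% 180
  expect_lte(min(d01, 180 - d01 + 90 - 90), 95)
  expect_gte(d01, 85)
})

test_that("an isotropic disk has no defined orientation", {
  m <- matrix(0, 41, 41)
  xx <- matrix(seq_len(41) - 21, 41, 41, byrow = TRUE)
  yy <- t(xx)
  disk <- xx^2 + yy^2 <= 15^2
  m[disk] <- 1
  r <- compute_anisotropy_orientation(m, disk)
  expect_false(r$defined)
  expect_lt(r$anisotropy_ratio, 1.1)
  expect_error(compute_anisotropy_orientation(m, disk & FALSE),
               class = "gcwmorph_input_error")
})
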