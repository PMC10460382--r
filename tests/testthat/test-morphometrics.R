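test_that("Max-Feret matches hand-computable cases", {
  g <- voxel_geometry()  # 0.17 um/px
  m <- matrix(FALSE, 5, 15); m[3, 3:13] <- TRUE       # 11-px run
  expect_equal(as.numeric(max_feret_diameter(m, g)), 10 * 0.17,
               tolerance = 1e-12)
  s <- matrix(FALSE, 5, 5); s[3, 3] <- TRUE           # singleton
  f <- max_feret_diameter(s, g)
  expect_identical(as.numeric(f), 0)
  expect_true(attr(f, "sub_resolution"))
  expect_error(max_feret_diameter(matrix(FALSE, 3, 3), g),
               class = "gcwmorph_input_error")
  disk <- granule_equator_mask(10)                    # 10-um disk
  expect_lte(abs(as.numeric(max_feret_diameter(disk, g)) - 10), 2 * 0.17)
})

test_that("Max-Feret equals the all-pairs brute force on random masks", {
  set.seed(404)
  g <- voxel_geometry()
  for (i in 1:25) {
    n <- sample(3:40, 1)
    m <- matrix(runif(n * n) < runif(1, 0.05, 0.6), n, n)
    if (!any(m)) m[1, 1] <- TRUE
    expect_equal(as.numeric(max_feret_diameter(m, g)), feret_oracle(m, g),
                 tolerance = 1e-12)
  }
})

test_that("size classes partition diameters with closed B boundaries", {
  expect_identical(as.character(classify_granule_size(c(4, 6, 22))),
                   c("C", "B", "A"))
  expect_identical(as.character(classify_granule_size(c(5, 15))), c("B", "B"))
  expect_identical(as.character(classify_granule_size(c(4.999, 15.001))),
                   c("C", "A"))
  d <- seq(0, 40, by = 0.25)
  cls <- classify_granule_size(d)
  expect_true(all(!is.na(cls)))
  expect_true(!is.unsorted(cls))   # monotone non-decreasing with d
  expect_error(classify_granule_size(-1), class = "gcwmorph_input_error")
})

test_that("spherical volumes follow pi d^3 / 6", {
  expect_identical(sphere_volume_from_feret(0), 0)
  expect_equal(sphere_volume_from_feret(2), 4 * pi / 3, tolerance = 1e-12)
  expect_equal(sphere_volume_from_feret(22), pi * 22^3 / 6, tolerance = 1e-12)
  expect_equal(round(sphere_volume_from_feret(22), 2), 5575.28)
})

test_that("size distributions sum to 100 and show the volume-number crossover", {
  lab <- array(0L, dim = c(200, 200, 3))
  # three granules on slice 2: diameters ~3, 8, 20 um
  for (spec in list(c(1, 30, 30, 9), c(2, 90, 90, 24), c(3, 150, 150, 59))) {
    mask <- granule_equator_mask(spec[4] * 0.17)
    n <- nrow(mask)
    r0 <- spec[2] - floor(n / 2); c0 <- spec[3] - floor(n / 2)
    sub <- lab[r0:(r0 + n - 1), c0:(c0 + n - 1), 2]
    sub[mask] <- spec[1]
    lab[r0:(r0 + n - 1), c0:(c0 + n - 1), 2] <- sub
  }
  sd_ <- size_distribution(label_map(lab), representative_z = 2)
  expect_equal(sum(sd_$by_class$number_pct), 100, tolerance = 1e-6)
  expect_equal(sum(sd_$by_class$volume_pct), 100, tolerance = 1e-6)
  expect_equal(sum(sd_$by_bin$number_pct), 100, tolerance = 1e-6)
  expect_identical(nrow(sd_$per_granule), 3L)
  byc <- sd_$by_class
  expect_gte(byc$volume_pct[byc$size_class == "A"],
             byc$number_pct[byc$size_class == "A"])
  expect_lte(byc$volume_pct[byc$size_class == "C"],
             byc$number_pct[byc$size_class == "C"])
})

test_that("crossover holds for any mixed synthetic population", {
  for (seed in 1:5) {
    pop <- sample_granule_population(simulation_params(), 200, seed = seed)
    per <- tibble::tibble(id = pop$id, z_slice = 1L,
                          max_feret_um = pop$true_diameter_um,
                          volume_um3 = sphere_volume_from_feret(pop$true_diameter_um),
                          size_class = pop$size_class)
    byc <- gcwmorph:::summarize_classes(per)
    if (any(byc$size_class == "A" & byc$n > 0)) {
      expect_gte(byc$volume_pct[byc$size_class == "A"],
                 byc$number_pct[byc$size_class == "A"])
    }
    expect_lte(byc$volume_pct[byc$size_class == "C"],
               byc$number_pct[byc$size_class == "C"])
  }
})

test_that("starch fraction handles the degenerate all/none cases", {
  d <- c(40, 40, 16)
  mask <- array(FALSE, dim = d); mask[10:30, 10:30, 2:15] <- TRUE
  env <- structure(list(mask = mask, z_start = 2L, z_end = 15L,
                        threshold = 1, empty = FALSE,
                        geometry = voxel_geometry()),
                   class = "gcw_envelope")
  lab_full <- array(0L, dim = d); lab_full[10:30, 10:30, ] <- 1L
  fr <- starch_fraction(label_map(lab_full), env)
  expect_equal(fr$mean, 1); expect_equal(fr$sd, 0)
  fr0 <- starch_fraction(label_map(array(0L, dim = d)), env)
  expect_equal(fr0$mean, 0); expect_equal(fr0$sd, 0)
  expect_error(starch_fraction(label_map(lab_full), env, n_slices = 1))
  expect_error(starch_fraction(label_map(lab_full), env, span_um = 20),
               class = "gcwmorph_input_error")
})

box_envelope <- function(l_px, w_px, z1, z2, dims, angle = 0) {
  mask <- array(FALSE, dim = dims)
  px <- 0.17
  cx <- dims[2] * px / 2; cy <- dims[1] * px / 2
  xx <- (seq_len(dims[2]) - 0.5) * px - cx
  yy <- (seq_len(dims[1]) - 0.5) * px - cy
  X <- matrix(xx, dims[1], dims[2], byrow = TRUE)
  Y <- matrix(yy, dims[1], dims[2])
  U <- X * cos(angle) + Y * sin(angle)
  V <- -X * sin(angle) + Y * cos(angle)
  sl <- abs(U) <= l_px * px / 2 & abs(V) <= w_px * px / 2
  for (k in z1:z2) mask[, , k] <- sl
  structure(list(mask = mask, z_start = as.integer(z1), z_end = as.integer(z2),
                 threshold = 1, empty = FALSE, geometry = voxel_geometry()),
            class = "gcw_envelope")
}

test_that("wall dimensions recover a synthetic box within a voxel", {
  # 20.4 x 6.8 um box over slices 3..14 (6 um depth)
  env <- box_envelope(120, 40, 3, 14, c(200, 200, 20))
  dims <- measure_gcw_dimensions(env)
  l_true <- sqrt(119^2 + 39^2) * 0.17  # diagonal of the pixel-centre box
  expect_lte(abs(dims$length_um - l_true), 2 * 0.17)
  expect_lte(abs(dims$depth_um - 6), 0.5)
  env30 <- box_envelope(120, 40, 3, 14, c(200, 200, 20), angle = pi / 6)
  dims30 <- measure_gcw_dimensions(env30)
  expect_lte(abs(dims30$length_um - dims$length_um), 3 * 0.17)
  expect_lte(abs(dims30$depth_um - dims$depth_um), 1e-9)
})

test_that("a tapered wall reports distinct mid, min and max widths", {
  dims_a <- c(160, 200, 10)
  mask <- array(FALSE, dim = dims_a)
  for (k in 3:8) {
    for (cc in 30:170) {
      w <- round(10 + (cc - 30) * 0.25)   # width grows along the length
      r0 <- 80 - w; r1 <- 80 + w
      mask[r0:r1, cc, k] <- TRUE
    }
  }
  env <- structure(list(mask = mask, z_start = 3L, z_end = 8L, threshold = 1,
                        empty = FALSE, geometry = voxel_geometry()),
                   class = "gcw_envelope")
  dims <- measure_gcw_dimensions(env)
  expect_lt(dims$width_min_um, dims$width_um)
  expect_lt(dims$width_um, dims$width_max_um)
})

test_that("wall classification follows the depth and width rules", {
  mk_dims <- function(D, W) structure(list(length_um = 100, width_um = W,
                                           width_min_um = W, width_max_um = W,
                                           depth_um = D, mid_slice = 1L),
                                      class = "gcw_dimensions")
  expect_identical(classify_wall_type(mk_dims(10, 11), 20)$wall_class, "string")
  expect_identical(classify_wall_type(mk_dims(19, 30), 20)$wall_class, "intact")
  # full-depth wall much wider than deep is intact by the depth rule
  expect_identical(classify_wall_type(mk_dims(20, 100), 20)$wall_class, "intact")
  mid <- classify_wall_type(mk_dims(14, 20), 20)
  expect_true(mid$indeterminate)
})
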