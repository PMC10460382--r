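test_that("a blank field yields zero labels; empty range warns", {
  blank <- array(0, dim = c(32, 32, 6))
  lm <- segment_granules(blank)
  expect_identical(lm$n_labels, 0L)
  r0 <- determine_analyzable_depth(blank)
  expect_warning(lm2 <- segment_granules(blank, r0))
  expect_identical(lm2$n_labels, 0L)
})

test_that("an isolated granule is segmented as one label with high IoU", {
  params <- simulation_params(target_starch_fraction = 0,
                              z_elongation_factor = 1, seed = 12)
  sc <- build_scene(params, wall_geometry("bulk", length_um = 18,
                                          width_um = 18, depth_um = 12),
                    canvas_px = c(128, 128), n_slices = 24)
  a <- 5
  sc$granules <- tibble::tibble(
    id = 1L, true_diameter_um = 10, a_um = a, b_um = a, c_um = a,
    orientation_rad = 0, size_class = "B",
    x_um = 128 * 0.17 / 2, y_um = 128 * 0.17 / 2, z_um = 6)
  g <- gcwmorph:::ellipsoid_grid(sc$granules$x_um, sc$granules$y_um, 6,
                                 a, a, a, 0, sc$dims, 0.17, 0.5)
  vox <- gcwmorph:::rasterize_ellipsoid(g, sc$dims, a)
  sc$truth_labels[] <- 0L
  sc$truth_labels[vox$idx] <- 1L
  chans <- gcwmorph:::render_shg_all(sc)
  combined <- Reduce(`+`, chans)
  combined <- apply_axial_elongation_and_noise(
    combined, params, seed = 1, elongate = FALSE)
  zr <- determine_analyzable_depth(combined)
  lm <- segment_granules(combined, zr)
  expect_identical(lm$n_labels, 1L)
  mm <- match_granules(lm, sc, zr)
  expect_gte(mm$iou[1], 0.7)
})

test_that("two granules a micrometre apart stay separate with true centres", {
  params <- simulation_params(target_starch_fraction = 0,
                              z_elongation_factor = 1, seed = 13)
  sc <- build_scene(params, wall_geometry("bulk", length_um = 18,
                                          width_um = 18, depth_um = 12),
                    canvas_px = c(128, 128), n_slices = 24)
  a <- 3; gap <- 1   # 1 um clearance between surfaces
  cx <- 128 * 0.17 / 2
  xs <- c(cx - a - gap / 2, cx + a + gap / 2)
  sc$granules <- tibble::tibble(
    id = 1:2, true_diameter_um = 2 * a, a_um = a, b_um = a, c_um = a,
    orientation_rad = 0, size_class = "B",
    x_um = xs, y_um = cx, z_um = 6)
  sc$truth_labels[] <- 0L
  for (i in 1:2) {
    g <- gcwmorph:::ellipsoid_grid(xs[i], cx, 6, a, a, a, 0, sc$dims, 0.17, 0.5)
    vox <- gcwmorph:::rasterize_ellipsoid(g, sc$dims, a)
    sc$truth_labels[vox$idx] <- i
  }
  chans <- gcwmorph:::render_shg_all(sc)
  combined <- apply_axial_elongation_and_noise(
    Reduce(`+`, chans), params, seed = 2, elongate = FALSE)
  zr <- determine_analyzable_depth(combined)
  lm <- segment_granules(combined, zr)
  expect_identical(lm$n_labels, 2L)
  mm <- match_granules(lm, sc, zr)
  expect_true(all(mm$center_offset_um <= 1))
})

test_that("granule count is recovered within 15% inside the analyzable depth", {
  # rendered without the axial-elongation artifact, so that a granule's
  # signal sits on its true position and in-range counting is well defined;
  # truth and detections are counted symmetrically by centroid slice
  n_true <- n_det <- 0
  for (spec in list(c(0.35, 101), c(0.45, 102), c(0.5, 42))) {
    p <- simulation_params(target_starch_fraction = spec[1],
                           seed = as.integer(spec[2]),
                           z_elongation_factor = 1)
    sim <- simulate_stack(p, wall_geometry("string", length_um = 20,
                                           width_um = 11, depth_um = 10),
                          canvas_px = c(160, 160), n_slices = 40)
    q <- quantify_stack(sim$stack)
    zr <- q$shg_range
    # interior window: labels cut at the range border have biased centroids,
    # so both counts use a margin inside the analyzable depth
    w_lo <- zr$z_start + 1; w_hi <- zr$z_end - 4
    ctr <- round(sim$truth$z_um / 0.5 + 0.5)
    n_true <- n_true + sum(ctr >= w_lo & ctr <= w_hi)
    lab <- q$labels$labels
    pos <- which(lab > 0L)
    kz <- (pos - 1L) %/% (dim(lab)[1] * dim(lab)[2]) + 1L
    cent <- round(tapply(kz, lab[pos], mean))
    n_det <- n_det + sum(cent >= w_lo & cent <= w_hi)
  }
  expect_lte(abs(n_det - n_true) / n_true, 0.15)
})

test_that("matched granules reach a median IoU of 0.5 on a dense scene", {
  sc <- bulk_scene()
  chans <- gcwmorph:::render_shg_all(sc)
  combined <- apply_axial_elongation_and_noise(
    Reduce(`+`, chans), sc$params, seed = 3)
  zr <- determine_analyzable_depth(combined)
  lm <- segment_granules(combined, zr)
  mm <- match_granules(lm, sc, zr)
  ctr_slice <- round(sc$granules$z_um / sc$geometry$z_step + 0.5)
  ids_in <- sc$granules$id[ctr_slice >= zr$z_start & ctr_slice <= zr$z_end]
  in_range <- mm[mm$truth_id %in% ids_in, ]
  expect_gte(median(in_range$iou), 0.5)
})

test_that("label interpolation fills gaps by signed-distance blending", {
  d <- c(40, 40, 5)
  mk_disk <- function(r) {
    xx <- matrix(seq_len(40) - 20, 40, 40, byrow = TRUE)
    yy <- t(xx)
    xx^2 + yy^2 <= r^2
  }
  lab <- array(0L, dim = d)
  lab[, , 1][mk_disk(7)] <- 1L
  lab[, , 3][mk_disk(7)] <- 1L
  out <- interpolate_labels(label_map(lab), key_slices = c(1, 3))
  expect_identical(out$labels[, , 2], lab[, , 1])

  lab2 <- array(0L, dim = d)
  lab2[, , 1][mk_disk(5)] <- 1L
  lab2[, , 3][mk_disk(9)] <- 1L
  out2 <- interpolate_labels(label_map(lab2), key_slices = c(1, 3))
  r_mid <- sqrt(sum(out2$labels[, , 2] == 1L) / pi)
  expect_lte(abs(r_mid - 7), 1)
})

test_that("interpolation copies single-slice labels and invents none", {
  d <- c(30, 30, 5)
  lab <- array(0L, dim = d)
  lab[5:10, 5:10, 1] <- 1L
  lab[5:10, 5:10, 5] <- 1L
  lab[20:24, 20:24, 1] <- 2L   # absent on slice 5
  out <- interpolate_labels(label_map(lab), key_slices = c(1, 5))
  expect_identical(attr(out, "copied_ids"), 2L)
  # copied through the gap unchanged
  expect_identical(out$labels[, , 3] == 2L, lab[, , 1] == 2L)
  ids_mid <- unique(as.vector(out$labels[, , 2:4]))
  expect_true(all(ids_mid %in% c(0L, 1L, 2L)))
})
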