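# Shared simulated scenes, built once per test run and memoised.
# Small canvases keep the suite fast while preserving the full pipeline
# behaviour (wall geometry, attenuation, elongation, noise).

.scene_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .scene_cache)) {
    assign(key, force(expr), envir = .scene_cache)
  }
  get(key, envir = .scene_cache)
}

small_string_sim <- function() {
  cached("string_sim", {
    p <- simulation_params(target_starch_fraction = 0.5, seed = 42)
    simulate_stack(p, wall_geometry("string", length_um = 20, width_um = 11,
                                    depth_um = 10),
                   canvas_px = c(160, 160), n_slices = 40)
  })
}

small_intact_sim <- function() {
  cached("intact_sim", {
    p <- simulation_params(target_starch_fraction = 0.5, seed = 43)
    simulate_stack(p, wall_geometry("intact", length_um = 20, width_um = 18,
                                    depth_um = 19),
                   canvas_px = c(160, 160), n_slices = 40)
  })
}

string_quant <- function() {
  cached("string_quant", quantify_stack(small_string_sim()$stack))
}

intact_quant <- function() {
  cached("intact_quant", quantify_stack(small_intact_sim()$stack))
}

# a bulk slab scene with many granules, for segmentation statistics
bulk_scene <- function() {
  cached("bulk_scene", {
    p <- simulation_params(target_starch_fraction = 0.45, seed = 99)
    build_scene(p, wall_geometry("bulk", length_um = 36, width_um = 30,
                                 depth_um = 12),
                canvas_px = c(256, 256), n_slices = 30)
  })
}

# brute-force Max-Feret oracle: all pixel-centre pairs
feret_oracle <- function(mask, geometry = voxel_geometry()) {
  pxl <- which(mask != 0, arr.ind = TRUE)
  if (nrow(pxl) == 1) return(0)
  best <- 0
  for (i in seq_len(nrow(pxl) - 1)) {
    d2 <- (pxl[(i + 1):nrow(pxl), 1] - pxl[i, 1])^2 +
          (pxl[(i + 1):nrow(pxl), 2] - pxl[i, 2])^2
    best <- max(best, max(d2))
  }
  sqrt(best) * geometry$pixel_size_xy
}

# rasterize one granule's equatorial cross-section as a 2D mask
granule_equator_mask <- function(d_um, orientation = 0, px = 0.17,
                                 aspect = 1) {
  a <- d_um / 2; b <- a * aspect
  n <- ceiling(2 * a / px) + 4
  xx <- (seq_len(n) - (n + 1) / 2) * px
  X <- matrix(xx, n, n, byrow = TRUE)
  Y <- matrix(xx, n, n)
  U <- X * cos(orientation) + Y * sin(orientation)
  V <- -X * sin(orientation) + Y * cos(orientation)
  (U / a)^2 + (V / b)^2 <= 1
}
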