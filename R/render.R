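# Separable Gaussian blur of a 3D array by shift-and-add with a truncated
# kernel (half-width 3 sigma).  Zero padding outside the volume.
blur3d <- function(arr, sigma) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (is.na(s) || s <= 0) next
    hw <- max(1L, ceiling(3 * s))
    w <- exp(-((-hw):hw)^2 / (2 * s^2))
    w <- w / sum(w)
    out <- array(0, dim = d)
    n <- d[ax]
    for (j in seq_along(w)) {
      off <- j - hw - 1L
      src <- (1 + max(0, off)):(n + min(0, off))
      dst <- src - off
      if (length(src) == 0) next
      if (ax == 1) out[dst, , ] <- out[dst, , ] + w[j] * arr[src, , ]
      else if (ax == 2) out[, dst, ] <- out[, dst, ] + w[j] * arr[, src, ]
      else out[, , dst] <- out[, , dst] + w[j] * arr[, , src]
    }
    arr <- out
  }
  arr
}

shg_attenuation <- function(n_slices, dz, atten_um) {
  exp(-((seq_len(n_slices) - 0.5) * dz) / atten_um)
}

# Bounding box of the non-zero region of a 3D array, padded (per axis) and
# clipped.
nonzero_box <- function(arr, pad = 0L) {
  d <- dim(arr)
  pad <- rep(as.integer(pad), length.out = 3)
  rs <- rowSums(arr != 0, dims = 1)
  cs <- colSums(arr != 0)           # nx x nz
  ks <- colSums(cs)                 # per-slice
  cs <- rowSums(cs)                 # per-column
  if (all(ks == 0)) return(NULL)
  rng <- function(v, n, p) c(max(1L, min(which(v > 0)) - p),
                             min(n, max(which(v > 0)) + p))
  list(r = rng(rs, d[1], pad[1]), c = rng(cs, d[2], pad[2]),
       k = rng(ks, d[3], pad[3]))
}

# Render all eight polarized SHG channels of a scene in one pass over the
# granules.  Per granule the radius fraction, radial angle and shell profile
# are computed once; the eight channels differ only by the angular lobe
# factor and the backward/forward radial weight.
render_shg_all <- function(scene, directions = c("backward", "forward"),
                           angles = c(0, 45, 90, 135)) {
  params <- scene$params
  dims <- scene$dims
  px <- scene$geometry$pixel_size_xy; dz <- scene$geometry$z_step
  att <- shg_attenuation(dims[3], dz, params$atten_length_shg_um)
  ny <- dims[1]; nx <- dims[2]
  out <- list()
  for (dir in directions) for (ang in angles) {
    out[[sprintf("SHG_%s_%03d", if (dir == "backward") "B" else "F", ang)]] <-
      array(0, dim = dims)
  }
  gr <- scene$granules
  p <- params$lobe_exponent
  h <- params$hilum_radius_frac
  for (i in seq_len(nrow(gr))) {
    g <- ellipsoid_grid(gr$x_um[i], gr$y_um[i], gr$z_um[i],
                        gr$a_um[i], gr$b_um[i], gr$c_um[i],
                        gr$orientation_rad[i], dims, px, dz)
    if (is.null(g)) next
    theta <- atan2(g$Y, g$X)          # lab-frame radial angle, in-plane
    base <- outer(g$rows, (g$cols - 1L) * ny, `+`)
    for (j in seq_along(g$slices)) {
      k <- g$slices[j]
      u2 <- g$q2d + (g$zz[j] / gr$c_um[i])^2
      sel <- u2 <= 1 & u2 >= h^2      # shell outside the dark hilum
      if (!any(sel)) next
      ur <- sqrt(u2[sel])             # radius fraction in [h, 1]
      th <- theta[sel]
      ii <- base[sel] + (k - 1L) * ny * nx
      for (dir in directions) {
        wdir <- if (dir == "backward") ur else 1 - ur
        tag <- if (dir == "backward") "B" else "F"
        for (ang in angles) {
          lobe <- abs(cos(th - ang * pi / 180))^p
          nm <- sprintf("SHG_%s_%03d", tag, ang)
          out[[nm]][ii] <- out[[nm]][ii] + wdir * lobe * att[k]
        }
      }
    }
  }
  out
}

#' Render one polarized SHG channel of a scene (noise-free)
#'
#' Granule SHG is modelled on concentric shells: the angular response is the
#' two-lobe law `|cos(theta_radial - theta_pol)|^p`, the centrosymmetric
#' hilum core (radius fraction `hilum_radius_frac`) is exactly zero, backward
#' detection is weighted towards the granule periphery and forward detection
#' towards the interior (complementary linear ramps in the radius fraction),
#' and the whole field decays as `exp(-z / atten_length_shg_um)`.  Gluten and
#' gas contribute no SHG.
#'
#' @param scene A [build_scene()] scene.
#' @param spec A [channel_spec()] with `modality = "SHG"`.
#' @return A 3D intensity array (pre-noise, pre-elongation).
#' @export
render_shg_channel <- function(scene, spec) {
  stopifnot(inherits(scene, "gcw_scene"))
  if (!inherits(spec, "channel_spec") || spec$modality != "SHG") {
    stop_input("`spec` must be an SHG channel_spec",
               class = "gcwmorph_modality_error")
  }
  render_shg_all(scene, directions = spec$direction,
                 angles = spec$polarization_deg)[[1]]
}

#' Render the endogenous-fluorescence channel of a scene (noise-free)
#'
#' The gluten network carries a high mean EF level modulated by a fibrillar
#' band-pass noise texture elongated along the wall axis; granule interiors
#' appear as dim (but non-zero) voids; gas is exactly zero.  The field decays
#' as `exp(-z / atten_length_ef_um)`, slower than SHG.
#'
#' @param scene A [build_scene()] scene.
#' @param seed Seed for the texture draw; defaults to `params$seed + 1`.
#' @return A 3D intensity array (pre-noise).
#' @export
render_ef_channel <- function(scene, seed = scene$params$seed + 1L) {
  stopifnot(inherits(scene, "gcw_scene"))
  params <- scene$params
  dims <- scene$dims
  dz <- scene$geometry$z_step
  gluten <- scene$wall & scene$truth_labels == 0L
  granule <- scene$truth_labels > 0L
  ef <- array(0, dim = dims)
  ef[gluten] <- params$gluten_ef_level
  ef[granule] <- params$granule_ef_level
  if (params$ef_texture_amp > 0 && any(gluten)) {
    # band-pass fibre texture, computed on the wall bounding box at half
    # resolution (fibres are several pixels wide, so this loses nothing)
    box <- nonzero_box(ef, pad = 2L)
    db <- c(box$r[2] - box$r[1] + 1L, box$c[2] - box$c[1] + 1L,
            box$k[2] - box$k[1] + 1L)
    dh <- pmax(ceiling(db / 2), 1L)
    tex <- with_seed(seed, array(rnorm(prod(dh)), dim = dh))
    # fibres elongated along the wall's long axis (x for the default layout)
    bp <- blur3d(tex, c(0.6, 2, 0.6)) - blur3d(tex, c(1.8, 4.5, 1.2))
    bp <- bp / max(sd(bp), 1e-12)
    up <- function(idx, n) pmin((idx + 1L) %/% 2L, n)
    mult_box <- pmax(1 + params$ef_texture_amp *
                       bp[up(seq_len(db[1]), dh[1]),
                          up(seq_len(db[2]), dh[2]),
                          up(seq_len(db[3]), dh[3]), drop = FALSE], 0.15)
    mult <- array(1, dim = dims)
    mult[box$r[1]:box$r[2], box$c[1]:box$c[2], box$k[1]:box$k[2]] <- mult_box
    ef[gluten] <- ef[gluten] * mult[gluten]
  }
  att <- shg_attenuation(dims[3], dz, params$atten_length_ef_um)
  for (k in seq_len(dims[3])) ef[, , k] <- ef[, , k] * att[k]
  ef
}

#' Apply the axial elongation artifact, detection PSF, and shot noise
#'
#' Emulates the tubular z-stretching of granules seen in SHG stacks of dough:
#' the field is resampled along z about its intensity-weighted centroid with
#' stretch factor `z_elongation_factor`, then blurred with an anisotropic
#' Gaussian PSF (axial sigma = `z_elongation_factor` x lateral sigma), and
#' finally signal-dependent (Poisson-like) noise is added:
#' `x + noise_scale * sqrt(x) * N(0,1)`, clipped at zero.
#'
#' With `z_elongation_factor = 1` and `noise_scale = 0` the field is returned
#' unchanged up to the PSF blur (and exactly unchanged if `psf_sigma_um = 0`).
#'
#' @param field 3D intensity array.
#' @param params A [simulation_params()].
#' @param geometry A [voxel_geometry()].
#' @param seed Seed for the noise draw; defaults to `params$seed + 2`.
#' @param elongate Apply the axial stretch (disable for EF, whose depth
#'   fidelity is unaffected by the artifact).
#' @return The degraded 3D intensity array; deterministic given the seed.
#' @export
apply_axial_elongation_and_noise <- function(field, params,
                                             geometry = voxel_geometry(),
                                             seed = params$seed + 2L,
                                             elongate = TRUE) {
  stopifnot(inherits(params, "simulation_params"))
  f <- params$z_elongation_factor
  if (f < 1) {
    stop_input("`z_elongation_factor` must be >= 1",
               class = "gcwmorph_parameter_error")
  }
  d <- dim(field)
  # all operations act on the (padded) non-zero bounding box: the stretch,
  # the PSF and the signal-dependent noise all leave true zeros untouched
  s_lat <- params$psf_sigma_um / geometry$pixel_size_xy
  s_ax <- f * params$psf_sigma_um / geometry$z_step
  pad_lat <- max(ceiling(3 * s_lat), 1L)
  pad_ax <- max(ceiling(3 * s_ax), 1L) +
    if (f > 1) ceiling(d[3] * (1 - 1 / f) / 2) + 1L else 0L
  box <- nonzero_box(field, pad = c(pad_lat, pad_lat, pad_ax))
  if (is.null(box)) return(field)
  sub <- field[box$r[1]:box$r[2], box$c[1]:box$c[2], box$k[1]:box$k[2],
               drop = FALSE]
  db <- dim(sub)
  tot <- sum(sub)
  if (elongate && f > 1 && tot > 0) {
    sums <- vapply(seq_len(db[3]), function(k) sum(sub[, , k]), numeric(1))
    zc <- sum(sums * seq_len(db[3])) / tot
    out <- array(0, dim = db)
    for (k in seq_len(db[3])) {
      src <- zc + (k - zc) / f
      k1 <- floor(src); w2 <- src - k1
      s1 <- if (k1 >= 1 && k1 <= db[3]) sub[, , k1] else 0
      s2 <- if (k1 + 1 >= 1 && k1 + 1 <= db[3]) sub[, , k1 + 1] else 0
      out[, , k] <- (1 - w2) * s1 + w2 * s2
    }
    sub <- out
  }
  if (params$psf_sigma_um > 0) {
    sub <- blur3d(sub, c(s_lat, s_lat, s_ax))
  }
  if (params$noise_scale > 0) {
    mx <- max(sub)
    if (mx > 0) {
      nrm <- sub / mx
      noisy <- with_seed(seed,
        nrm + params$noise_scale * sqrt(pmax(nrm, 0)) *
          array(rnorm(length(nrm)), dim = db))
      sub <- pmax(noisy, 0) * mx
    }
  }
  out <- array(0, dim = d)
  out[box$r[1]:box$r[2], box$c[1]:box$c[2], box$k[1]:box$k[2]] <- sub
  out
}

#' Simulate a full nine-channel polarized SHG + EF acquisition
#'
#' Builds a ground-truthed scene, renders the eight polarized SHG channels
#' (backward/forward x 0/45/90/135 degrees) and the EF channel, applies the
#' axial elongation artifact (SHG only), PSF blur and shot noise, and
#' quantizes all channels jointly to the 16-bit grid.  Byte-identical output
#' is guaranteed for a fixed `params$seed`.
#'
#' @param params A [simulation_params()].
#' @param wall A [wall_geometry()].
#' @param geometry A [voxel_geometry()].
#' @param canvas_px Canvas `(nx, ny)` in pixels (default the full-frame
#'   1024 x 1024 acquisition format).
#' @param n_slices Number of z-slices (default 84, a deep GCW stack).
#' @param noise Disable to obtain the clean (pre-noise) stack.
#' @return An object of class `gcw_simulation`: `stack` (an [image_stack()]),
#'   `truth` (tibble of placed granules), `scene` (the full [build_scene()]
#'   object, including the wall mask and truth label array), and
#'   `achieved_fraction`.
#' @export
simulate_stack <- function(params, wall = wall_geometry("string"),
                           geometry = voxel_geometry(),
                           canvas_px = c(1024, 1024), n_slices = 84,
                           noise = TRUE) {
  scene <- build_scene(params, wall, geometry, canvas_px, n_slices)
  degrade <- if (noise) params else simulation_params_no_noise(params)
  chans <- render_shg_all(scene)
  chans$EF <- render_ef_channel(scene)
  nm <- names(chans)
  for (i in seq_along(chans)) {
    chans[[i]] <- apply_axial_elongation_and_noise(
      chans[[i]], degrade, geometry,
      seed = params$seed + 101L * i,
      elongate = nm[i] != "EF")
  }
  mx <- max(vapply(chans, max, numeric(1)))
  scale <- if (mx > 0) 0.9 * 65535 / mx else 1
  for (i in seq_along(chans)) chans[[i]] <- round(chans[[i]] * scale)
  specs <- default_channels()
  stack <- image_stack(chans[names(specs)], specs, geometry)
  structure(list(stack = stack, truth = scene$granules, scene = scene,
                 achieved_fraction = scene$achieved_fraction),
            class = "gcw_simulation")
}

simulation_params_no_noise <- function(params) {
  params$noise_scale <- 0
  params
}

#' @export
print.gcw_simulation <- function(x, ...) {
  cat(sprintf("<gcw_simulation> %s wall, %d granules, starch fraction %.3f\n",
              x$scene$wall_geometry$kind, nrow(x$truth), x$achieved_fraction))
  print(x$stack)
  invisible(x)
}
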