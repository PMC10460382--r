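#' Fuse polarized backward/forward SHG channels into one starch image
#'
#' Voxelwise sum (default) or maximum over all SHG channels — both detection
#' directions and all polarization angles — rescaled back to the dynamic
#' range of the input channels.  The summed reconstruction turns the
#' angle-dependent two-lobe granule signal into a complete outline of every
#' granule, which is what makes automated segmentation possible.
#'
#' @param stack An [image_stack()] containing at least one SHG channel.
#' @param method `"sum"` (default) or `"max"`.
#' @return A 3D intensity array with a `geometry` attribute.
#' @export
combine_polarizations <- function(stack, method = c("sum", "max")) {
  stopifnot(inherits(stack, "image_stack"))
  method <- match.arg(method)
  shg <- shg_channel_names(stack)
  if (length(shg) == 0) {
    stop_input("stack contains no SHG channel",
               class = "gcwmorph_input_error")
  }
  fields <- stack$voxels[shg]
  out <- fields[[1]]
  if (length(fields) > 1) {
    for (i in 2:length(fields)) {
      out <- if (method == "sum") out + fields[[i]] else pmax(out, fields[[i]])
    }
  }
  m_in <- max(vapply(fields, max, numeric(1)))
  m_out <- max(out)
  if (m_out > 0) out <- out * (m_in / m_out)
  attr(out, "geometry") <- stack$geometry
  out
}

#' Determine the depth range usable for segmentation
#'
#' Finds the largest contiguous run of slices — starting at the first slice
#' that reaches `contrast_floor` times the reference intensity — whose
#' robust maximum (99th percentile) stays at or above that floor.  The
#' reference is the robust maximum of the brightest slice, which makes the
#' criterion insensitive to dim leading slices.  Deeper slices are
#' considered too dim to segment and are discarded as a contiguous block,
#' mirroring slice-level truncation of SHG stacks.
#'
#' @param field 3D intensity array.
#' @param contrast_floor Fraction of the reference slice's robust maximum,
#'   in (0, 1).  Default 0.1.
#' @param geometry A [voxel_geometry()].
#' @return An object of class `depth_range`: `z_start`, `z_end` (inclusive
#'   slice indices), `n_slices`, `depth_um`, and `empty` (TRUE when the field
#'   carries no signal at all, in which case the range is flagged empty).
#' @export
determine_analyzable_depth <- function(field, contrast_floor = 0.1,
                                       geometry = voxel_geometry()) {
  if (contrast_floor <= 0 || contrast_floor >= 1) {
    stop_input("`contrast_floor` must be in (0, 1)")
  }
  nz <- dim(field)[3]
  q <- vapply(seq_len(nz), function(k) quantile(field[, , k], 0.99, names = FALSE),
              numeric(1))
  ref <- max(q)
  if (ref <= 0) {
    return(structure(list(z_start = NA_integer_, z_end = NA_integer_,
                          n_slices = 0L, depth_um = 0, empty = TRUE),
                     class = "depth_range"))
  }
  first <- which(q >= contrast_floor * ref)[1]
  ok <- q[first:nz] >= contrast_floor * ref
  n <- if (all(ok)) length(ok) else which(!ok)[1] - 1L
  structure(list(z_start = as.integer(first),
                 z_end = as.integer(first + n - 1L),
                 n_slices = as.integer(n),
                 depth_um = n * geometry$z_step,
                 empty = FALSE),
            class = "depth_range")
}

#' @export
print.depth_range <- function(x, ...) {
  if (x$empty) cat("<depth_range> empty (no signal)\n")
  else cat(sprintf("<depth_range> slices %d..%d (%d slices, %.1f um)\n",
                   x$z_start, x$z_end, x$n_slices, x$depth_um))
  invisible(x)
}

#' Principal orientation of an anisotropic (two-lobe) signal
#'
#' Intensity-weighted second-moment orientation of the masked signal in a 2D
#' slice, in degrees within `[0, 180)`, measured from the +x (column) axis.
#' For a polarized SHG granule image the two lobes align with the excitation
#' polarization, so the recovered orientation tracks the polarization angle.
#' A near-isotropic signal (axis ratio < 1.1) is flagged as undefined.
#'
#' @param field 2D intensity matrix.
#' @param mask 2D logical matrix selecting the granule.
#' @return A list: `angle_deg` (NA when undefined), `anisotropy_ratio`
#'   (square root of the eigenvalue ratio), `defined`.
#' @export
compute_anisotropy_orientation <- function(field, mask) {
  if (!any(mask)) {
    stop_input("`mask` is empty", class = "gcwmorph_input_error")
  }
  w <- field * mask
  tot <- sum(w)
  if (tot <= 0) {
    return(list(angle_deg = NA_real_, anisotropy_ratio = 1, defined = FALSE))
  }
  nr <- nrow(field); nc <- ncol(field)
  X <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  Y <- matrix(seq_len(nr), nr, nc)
  xc <- sum(w * X) / tot; yc <- sum(w * Y) / tot
  mu20 <- sum(w * (X - xc)^2) / tot
  mu02 <- sum(w * (Y - yc)^2) / tot
  mu11 <- sum(w * (X - xc) * (Y - yc)) / tot
  ev <- eigen(matrix(c(mu20, mu11, mu11, mu02), 2, 2), symmetric = TRUE)$values
  ratio <- sqrt(max(ev[1], 1e-12) / max(ev[2], 1e-12))
  ang <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  ang <- ang %% 180
  if (ratio < 1.1) {
    list(angle_deg = NA_real_, anisotropy_ratio = ratio, defined = FALSE)
  } else {
    list(angle_deg = ang, anisotropy_ratio = ratio, defined = TRUE)
  }
}

#' Outline coverage of ground-truth granules in an intensity field
#'
#' For each placed granule, the fraction of its true outline-shell voxels
#' (radius fraction within `shell`, near the granule's equatorial plane)
#' whose intensity reaches `rel_threshold` times the granule's own robust
#' shell maximum.  The equatorial restriction keeps the measure an
#' in-plane (x-y) outline-completeness score, unconfounded by the depth
#' attenuation across the granule body.  Used to quantify how completely a
#' single polarization angle — versus the fused reconstruction — images
#' each granule outline.
#'
#' @param field 3D intensity array.
#' @param scene The [build_scene()] scene providing ground truth.
#' @param z_range Optional [determine_analyzable_depth()] range restricting
#'   the evaluation.
#' @param shell Radius-fraction interval of the outline shell.
#' @param rel_threshold Fraction of the granule's robust (99th percentile)
#'   shell intensity counted as "imaged".
#' @param equator_frac Half-width of the equatorial band as a fraction of
#'   the polar semi-axis.
#' @param min_voxels Granules with fewer in-range shell voxels are skipped.
#' @return A tibble: `id`, `coverage`, `n_shell`.
#' @export
outline_coverage <- function(field, scene, z_range = NULL,
                             shell = c(0.75, 1), rel_threshold = 0.15,
                             equator_frac = 0.35, min_voxels = 30) {
  stopifnot(inherits(scene, "gcw_scene"))
  px <- scene$geometry$pixel_size_xy; dz <- scene$geometry$z_step
  dims <- scene$dims
  ny <- dims[1]; nx <- dims[2]
  zlim <- if (is.null(z_range)) c(1L, dims[3]) else c(z_range$z_start, z_range$z_end)
  gr <- scene$granules
  res <- vector("list", nrow(gr))
  for (i in seq_len(nrow(gr))) {
    g <- ellipsoid_grid(gr$x_um[i], gr$y_um[i], gr$z_um[i],
                        gr$a_um[i], gr$b_um[i], gr$c_um[i],
                        gr$orientation_rad[i], dims, px, dz)
    if (is.null(g)) next
    base <- outer(g$rows, (g$cols - 1L) * ny, `+`)
    idx <- integer(0)
    for (j in seq_along(g$slices)) {
      k <- g$slices[j]
      if (k < zlim[1] || k > zlim[2]) next
      if (abs(g$zz[j]) > equator_frac * gr$c_um[i]) next
      u2 <- g$q2d + (g$zz[j] / gr$c_um[i])^2
      sel <- u2 >= shell[1]^2 & u2 <= shell[2]^2
      if (any(sel)) idx <- c(idx, base[sel] + (k - 1L) * ny * nx)
    }
    if (length(idx) < min_voxels) next
    vals <- field[idx]
    q <- quantile(vals, 0.99, names = FALSE)
    cov <- if (q <= 0) 0 else mean(vals >= rel_threshold * q)
    res[[i]] <- tibble::tibble(id = gr$id[i],
                               coverage = cov,
                               n_shell = length(idx))
  }
  dplyr::bind_rows(res)
}
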