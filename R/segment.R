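# Pooled-histogram Otsu threshold on values in [0, 1].
otsu_threshold <- function(v, n_levels = 256) {
  v <- v[is.finite(v)]
  v <- pmin(pmax(v, 0), 1)
  h <- tabulate(pmin(floor(v * n_levels) + 1L, n_levels), nbins = n_levels)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(n_levels) - 0.5) / n_levels)
  mu_t <- mu[n_levels]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- 0
  k <- which.max(sb2)
  (k - 0.5) / n_levels
}

# Minimal union-find with path halving.
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Segment starch granules from the fused SHG image
#'
#' Automated surrogate for slice-wise manual granule tracing.  Within the
#' analyzable depth only: each slice is attenuation-normalized by its robust
#' maximum, smoothed, thresholded (pooled Otsu by default), holes are filled
#' (capturing the dark hilum inside the bright shell) and the mask
#' morphologically closed; touching granules are split by a watershed on the
#' in-plane distance transform; 2D regions are then linked across slices by
#' mutual overlap into 3D granules.  All steps are deterministic.
#'
#' @param combined 3D fused SHG array from [combine_polarizations()].
#' @param z_range A [determine_analyzable_depth()] range (or `NULL` for the
#'   full stack).  Labels outside the range are empty.
#' @param geometry A [voxel_geometry()].
#' @param smooth_sigma_px Gaussian smoothing sigma, pixels.
#' @param threshold Intensity threshold on the normalized image; `NULL` uses
#'   pooled Otsu.
#' @param close_radius_px Radius of the morphological closing brush
#'   (small, so thin gluten films between touching granules survive).
#' @param watershed_tolerance,watershed_ext Watershed object-merging
#'   tolerance (distance units) and local-maximum neighbourhood radius.
#' @param link_min_overlap Minimum overlap, as a fraction of the smaller
#'   region, linking 2D regions on consecutive slices into one granule.
#' @param min_voxels 3D granules smaller than this are discarded.
#' @return A [label_map()] of the full stack depth.
#' @export
segment_granules <- function(combined, z_range = NULL,
                             geometry = voxel_geometry(),
                             smooth_sigma_px = 1,
                             threshold = NULL,
                             close_radius_px = 1,
                             watershed_tolerance = 1,
                             watershed_ext = 3,
                             link_min_overlap = 0.5,
                             min_voxels = 8) {
  d <- dim(combined)
  if (!is.null(z_range) && inherits(z_range, "depth_range") && z_range$empty) {
    warn("empty analyzable depth: returning an empty label map")
    return(label_map(array(0L, dim = d), geometry))
  }
  zs <- if (is.null(z_range)) 1L else z_range$z_start
  ze <- if (is.null(z_range)) d[3] else z_range$z_end
  nz <- ze - zs + 1L
  ny <- d[1]; nx <- d[2]

  # attenuation-normalized, smoothed slices
  norm <- array(0, dim = c(ny, nx, nz))
  for (j in seq_len(nz)) {
    sl <- combined[, , zs + j - 1L]
    q <- quantile(sl, 0.99, names = FALSE)
    if (q > 0) norm[, , j] <- pmin(sl / q, 1.5)
  }
  if (smooth_sigma_px > 0) {
    norm <- blur3d(norm, c(smooth_sigma_px, smooth_sigma_px, 0))
  }
  if (is.null(threshold)) threshold <- otsu_threshold(pmin(norm, 1))

  brush <- EBImage::makeBrush(2L * close_radius_px + 1L, shape = "disc")
  slice_labels <- vector("list", nz)
  n_regions <- integer(nz)
  for (j in seq_len(nz)) {
    bw <- norm[, , j] > threshold
    if (!any(bw)) { slice_labels[[j]] <- matrix(0L, ny, nx); next }
    bw <- EBImage::fillHull(bw)
    bw <- EBImage::closing(bw, brush)
    bw <- EBImage::fillHull(bw)
    dm <- EBImage::distmap(bw)
    ws <- EBImage::watershed(dm, tolerance = watershed_tolerance,
                             ext = watershed_ext)
    slice_labels[[j]] <- matrix(as.integer(ws), ny, nx)
    n_regions[j] <- max(slice_labels[[j]])
  }

  # link 2D regions on consecutive slices by overlap (union-find)
  offset <- c(0L, cumsum(n_regions))
  total <- offset[nz + 1L]
  if (total == 0L) return(label_map(array(0L, dim = d), geometry))
  parent <- uf_new(total)
  union <- function(i, j) {
    ri <- uf_find(parent, i); rj <- uf_find(parent, j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (j in seq_len(nz - 1L)) {
    l1 <- slice_labels[[j]]; l2 <- slice_labels[[j + 1L]]
    if (n_regions[j] == 0L || n_regions[j + 1L] == 0L) next
    a1 <- tabulate(l1[l1 > 0L], nbins = n_regions[j])
    a2 <- tabulate(l2[l2 > 0L], nbins = n_regions[j + 1L])
    sel <- l1 > 0L & l2 > 0L
    if (!any(sel)) next
    key <- (l1[sel] - 1L) * n_regions[j + 1L] + l2[sel]
    tab <- tabulate(key, nbins = n_regions[j] * n_regions[j + 1L])
    hit <- which(tab > 0L)
    for (hk in hit) {
      i1 <- (hk - 1L) %/% n_regions[j + 1L] + 1L
      i2 <- (hk - 1L) %% n_regions[j + 1L] + 1L
      if (tab[hk] >= link_min_overlap * min(a1[i1], a2[i2])) {
        union(offset[j] + i1, offset[j + 1L] + i2)
      }
    }
  }
  roots <- vapply(seq_len(total), function(i) uf_find(parent, i), integer(1))
  new_id <- integer(total)
  next_id <- 0L
  for (i in seq_len(total)) {     # first-appearance order: deterministic
    r <- roots[i]
    if (new_id[r] == 0L) { next_id <- next_id + 1L; new_id[r] <- next_id }
    new_id[i] <- new_id[r]
  }

  labels <- array(0L, dim = d)
  for (j in seq_len(nz)) {
    l <- slice_labels[[j]]
    pos <- l > 0L
    l[pos] <- new_id[offset[j] + l[pos]]
    labels[, , zs + j - 1L] <- l
  }

  # drop sub-resolution fragments, relabel contiguously
  sizes <- tabulate(labels[labels > 0L], nbins = next_id)
  keep <- which(sizes >= min_voxels)
  remap <- integer(next_id)
  remap[keep] <- seq_along(keep)
  pos <- labels > 0L
  labels[pos] <- remap[labels[pos]]
  label_map(labels, geometry)
}

signed_distance <- function(mask) {
  m <- EBImage::distmap(mask)
  out <- EBImage::distmap(1 - mask)
  m - out
}

#' Interpolate granule labels between key slices
#'
#' Fills the slices between manually (or sparsely) labelled key slices by
#' per-label signed-distance interpolation: for every label present on both
#' bounding key slices, the signed distance fields of its two masks are
#' linearly blended and thresholded at zero.  A label present on only one
#' bounding slice is copied through the gap and flagged.  Conflicting claims
#' on a voxel go to the label with the larger interpolated signed distance
#' (ties to the lower id).  No label absent from both bounding slices is
#' ever created.
#'
#' @param labels A [label_map()] whose non-empty slices include `key_slices`.
#' @param key_slices Sorted integer vector of key slice indices.
#' @return A [label_map()] with intermediate slices filled; the ids flagged
#'   as single-slice copies are in `attr(, "copied_ids")`.
#' @export
interpolate_labels <- function(labels, key_slices) {
  stopifnot(inherits(labels, "label_map"))
  key_slices <- sort(unique(as.integer(key_slices)))
  if (any(diff(key_slices) < 1)) {
    stop_input("`key_slices` must be strictly increasing")
  }
  arr <- labels$labels
  d <- dim(arr)
  out <- array(0L, dim = d)
  for (k in key_slices) out[, , k] <- arr[, , k]
  copied <- integer(0)
  for (gidx in seq_len(length(key_slices) - 1L)) {
    k1 <- key_slices[gidx]; k2 <- key_slices[gidx + 1L]
    if (k2 - k1 < 2L) next
    l1 <- arr[, , k1]; l2 <- arr[, , k2]
    ids <- sort(unique(c(l1[l1 > 0L], l2[l2 > 0L])))
    if (length(ids) == 0L) next
    sds <- lapply(ids, function(id) {
      m1 <- l1 == id; m2 <- l2 == id
      on1 <- any(m1); on2 <- any(m2)
      if (on1 && on2) {
        list(sd1 = signed_distance(m1), sd2 = signed_distance(m2), mode = "interp")
      } else if (on1) {
        list(sd1 = signed_distance(m1), sd2 = NULL, mode = "copy1")
      } else {
        list(sd1 = NULL, sd2 = signed_distance(m2), mode = "copy2")
      }
    })
    modes <- vapply(sds, function(s) s$mode, character(1))
    copied <- c(copied, ids[modes != "interp"])
    for (k in (k1 + 1L):(k2 - 1L)) {
      w <- (k - k1) / (k2 - k1)
      best <- matrix(-Inf, d[1], d[2])
      lab <- matrix(0L, d[1], d[2])
      for (ii in seq_along(ids)) {
        s <- sds[[ii]]
        sdk <- switch(s$mode,
                      interp = (1 - w) * s$sd1 + w * s$sd2,
                      copy1 = s$sd1,
                      copy2 = s$sd2)
        won <- sdk > 0 & sdk > best
        if (any(won)) { lab[won] <- ids[ii]; best[won] <- sdk[won] }
      }
      out[, , k] <- lab
    }
  }
  res <- label_map(out, labels$geometry)
  attr(res, "copied_ids") <- sort(unique(copied))
  res
}
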